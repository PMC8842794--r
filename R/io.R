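#' Read a gene-by-sample expression matrix with group labels
#'
#' The matrix file is tab-separated with the gene (or probe) identifier in
#' the first column and a header row of sample ids. The group file is a
#' two-column tab-separated table with header `sample<TAB>group`.
#'
#' @param path Path to the matrix TSV.
#' @param group_file Path to the sample-to-group TSV.
#' @param flavor `"intensity"` or `"counts"`.
#' @return An [expression_matrix()] object; row order is preserved.
#' @export
read_expression_matrix <- function(path, group_file,
                                   flavor = c("intensity", "counts")) {
  flavor <- match.arg(flavor)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup)) {
    stop("duplicate sample id(s) in header of '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in '%s'",
                   vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                   samples[bad[1, 2]], path), call. = FALSE)
    }
  }
  dimnames(num) <- list(ids, samples)
  grp <- utils::read.delim(group_file, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("sample", "group") %in% names(grp))) {
    stop("group file must have columns 'sample' and 'group'", call. = FALSE)
  }
  missing_grp <- setdiff(samples, grp$sample)
  if (length(missing_grp)) {
    stop("sample(s) in matrix missing from group file: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  expression_matrix(num, stats::setNames(grp$group, grp$sample)[samples],
                    flavor = flavor)
}

#' Write an expression matrix and its group table
#'
#' @param expr An `ExpressionMatrix`.
#' @param path Output path for the matrix TSV.
#' @param group_file Output path for the sample/group TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path, group_file) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(expr$groups), group = unname(expr$groups)),
    group_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set collection from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member<TAB>member...`; members
#' are deduplicated per set.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields in '%s'",
                 short[1], path), call. = FALSE)
  }
  nm <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  gene_set_collection(sets, desc)
}

#' Write a gene set collection to a GMT file
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network from a two-column edge list
#'
#' Directed input is collapsed to an undirected simple graph; self-loops
#' are dropped with a message reporting how many.
#'
#' @param path Path to the tab-separated edge list (no header).
#' @param directed_input Whether the file lists directed interactions
#'   (collapsed regardless; the flag only documents provenance).
#' @return An undirected simple `igraph` graph.
#' @export
read_edge_list <- function(path, directed_input = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(interaction_network(matrix(character(0), ncol = 2)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop(sprintf("edge list line %d has fewer than 2 columns in '%s'",
                 which(lengths(fields) < 2)[1], path), call. = FALSE)
  }
  em <- t(vapply(fields, `[`, character(2), 1:2))
  if (any(!nzchar(em))) {
    stop(sprintf("blank endpoint on edge list line %d in '%s'",
                 which(rowSums(!nzchar(em)) > 0)[1], path), call. = FALSE)
  }
  interaction_network(em)
}

#' Write an interaction network as a two-column edge list
#' @param net An `igraph` network.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  em <- igraph::as_edgelist(net, names = TRUE)
  writeLines(if (nrow(em)) paste(em[, 1], em[, 2], sep = "\t") else character(0),
             path)
  invisible(path)
}

#' Read a clinical table and join it to expression into a survival cohort
#'
#' The clinical TSV must carry header columns `sample`, `time`, `event`.
#'
#' @param path Path to the clinical TSV.
#' @param expr Gene-by-sample numeric matrix or `ExpressionMatrix` whose
#'   samples are matched by id to the clinical table.
#' @return A [survival_cohort()].
#' @export
read_clinical <- function(path, expr) {
  cl <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = c("character", "numeric", "integer"))
  if (!all(c("sample", "time", "event") %in% names(cl))) {
    stop("clinical file must have columns 'sample', 'time', 'event'",
         call. = FALSE)
  }
  if (anyDuplicated(cl$sample)) {
    stop("duplicate sample id(s) in clinical file", call. = FALSE)
  }
  m <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  common <- intersect(colnames(m), cl$sample)
  if (!length(common)) stop("no samples shared between clinical table and expression",
                            call. = FALSE)
  cl <- cl[match(common, cl$sample), ]
  survival_cohort(stats::setNames(cl$time, cl$sample),
                  stats::setNames(cl$event, cl$sample),
                  m[, common, drop = FALSE])
}

#' Write the clinical part of a survival cohort
#' @param cohort A `SurvivalCohort`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(cohort, path) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  utils::write.table(
    data.frame(sample = cohort$samples, time = cohort$time,
               event = cohort$event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulator-to-target table
#'
#' Three tab-separated header columns: `regulator`, `class` (TF or
#' cofactor), `target`; one row per regulator-target pair.
#'
#' @param path Path to the TSV.
#' @return A [tf_target_map()].
#' @export
read_tf_targets <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (!all(c("regulator", "class", "target") %in% names(tb))) {
    stop("TF target file must have columns 'regulator', 'class', 'target'",
         call. = FALSE)
  }
  if (!nrow(tb)) return(tf_target_map(list()))
  regs <- unique(tb$regulator)
  tf_target_map(
    stats::setNames(lapply(regs, function(r) tb$target[tb$regulator == r]),
                    regs),
    class = vapply(regs, function(r) tb$class[tb$regulator == r][1],
                   character(1))
  )
}

#' Write a regulator-to-target table
#' @param tf_map A `TFTargetMap`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tf_targets <- function(tf_map, path) {
  stopifnot(inherits(tf_map, "TFTargetMap"))
  rows <- do.call(rbind, lapply(names(tf_map$targets), function(r) {
    data.frame(regulator = r, class = tf_map$class[[r]],
               target = tf_map$targets[[r]], stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(regulator = character(0), class = character(0),
                       target = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
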