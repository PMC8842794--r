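#' Construct an expression matrix with group labels
#'
#' The central data container of the pipeline: a gene-by-sample numeric
#' matrix tagged with a measurement flavor (`"intensity"` for log2-scale
#' array intensities, `"counts"` for raw sequencing counts) and a
#' sample-to-group assignment. Optionally carries a probe-to-gene map when
#' rows are array probes rather than gene symbols.
#'
#' Gene and sample identifiers are matched case-sensitively and by exact
#' string everywhere in the package; no case folding or alias resolution is
#' performed.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene or probe
#'   ids), samples in columns (colnames = sample ids).
#' @param groups Named character vector mapping every sample id to a group
#'   label.
#' @param flavor `"intensity"` (log2 scale) or `"counts"` (non-negative
#'   integers).
#' @param probe_map Optional named character vector mapping probe id to
#'   gene symbol.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, groups,
                              flavor = c("intensity", "counts"),
                              probe_map = NULL) {
  flavor <- match.arg(flavor)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'; missing values are not allowed",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  missing_grp <- setdiff(colnames(values), names(groups))
  if (length(missing_grp)) {
    stop("sample(s) without group label: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  if (flavor == "counts" && (any(values < 0) || any(values != round(values)))) {
    stop("counts flavor requires non-negative integer values", call. = FALSE)
  }
  structure(
    list(values = values,
         groups = as.character(groups[colnames(values)]) |>
           stats::setNames(colnames(values)),
         flavor = flavor,
         probe_map = probe_map),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples; groups: %s\n",
              x$flavor, nrow(x$values), ncol(x$values),
              paste(sprintf("%s (n=%d)", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Sample ids belonging to one group
#' @param expr An `ExpressionMatrix`.
#' @param group Group label.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(expr, group) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  names(expr$groups)[expr$groups == group]
}

#' Construct a gene set collection
#'
#' A named list of character vectors of gene symbols, the in-memory form of
#' a GMT file. Set names must be unique and sets non-empty; members are
#' deduplicated.
#'
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled to empty strings).
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("every gene set needs a name", call. = FALSE)
    }
    dup <- names(sets)[duplicated(names(sets))]
    if (length(dup)) {
      stop("duplicate gene set name(s): ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    }
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(lengths(sets) == 0)) {
      stop("empty gene set(s): ",
           paste(names(sets)[lengths(sets) == 0], collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets))),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Construct an undirected simple interaction network
#'
#' Protein-protein interaction networks are represented as undirected
#' simple `igraph` graphs over gene symbols: self-loops and parallel edges
#' are removed on construction, and directed input is collapsed (the two
#' network statistics used downstream, interaction count and largest
#' connected component, are orientation-free).
#'
#' @param edges Two-column character matrix or data frame of endpoints, or
#'   an `igraph` object.
#' @param nodes Optional character vector of node names to include even if
#'   isolated.
#' @return An undirected simple `igraph` graph.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  if (inherits(edges, "igraph")) {
    g <- igraph::as_undirected(edges, mode = "collapse")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    return(g)
  }
  em <- as.matrix(edges)
  if (length(em) && ncol(em) != 2) {
    stop("`edges` must have two columns", call. = FALSE)
  }
  storage.mode(em) <- "character"
  if (length(em) && any(!nzchar(em) | is.na(em))) {
    stop("blank edge endpoint", call. = FALSE)
  }
  all_nodes <- unique(c(as.vector(t(em)), nodes))
  g <- igraph::graph_from_data_frame(
    as.data.frame(em, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = if (length(all_nodes)) all_nodes else NULL
  )
  n_loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops > 0) {
    message(sprintf("interaction_network: dropped %d self-loop(s)", n_loops))
  }
  g
}

#' Construct a survival cohort
#'
#' Per-sample follow-up time and event indicator joined to a gene-by-sample
#' expression matrix, the input of the univariate Cox screen and the
#' Kaplan-Meier median split.
#'
#' @param time Positive numeric vector of follow-up times (one consistent
#'   unit throughout).
#' @param event Integer vector in \{0, 1\}; 1 = death observed, 0 =
#'   censored.
#' @param expr Numeric gene-by-sample matrix with rownames (genes) and
#'   colnames (samples) aligned with `time`/`event` order, or named
#'   `time`/`event` matched by sample id.
#' @return Object of class `SurvivalCohort` with elements `time`, `event`,
#'   `expr`, `samples`.
#' @export
survival_cohort <- function(time, event, expr) {
  if (!is.matrix(expr) || is.null(colnames(expr)) || is.null(rownames(expr))) {
    stop("`expr` must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  }
  samples <- colnames(expr)
  if (!is.null(names(time))) time <- time[samples]
  if (!is.null(names(event))) event <- event[samples]
  if (length(time) != length(samples) || length(event) != length(samples)) {
    stop("`time` and `event` must cover every sample", call. = FALSE)
  }
  if (anyNA(time) || any(time <= 0)) {
    stop("all follow-up times must be positive", call. = FALSE)
  }
  if (anyNA(event) || !all(event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  structure(list(time = as.numeric(time),
                 event = as.integer(event),
                 expr = expr,
                 samples = samples),
            class = "SurvivalCohort")
}

#' @export
print.SurvivalCohort <- function(x, ...) {
  cat(sprintf("SurvivalCohort: %d samples (%d events), %d genes\n",
              length(x$samples), sum(x$event), nrow(x$expr)))
  invisible(x)
}

#' Construct a regulator-to-target annotation map
#'
#' Maps each transcription factor (or TF cofactor) to its set of annotated
#' target genes, used to count how many pathway genes each regulator
#' controls.
#'
#' @param targets Named list: regulator symbol -> character vector of
#'   target gene symbols.
#' @param class Character vector (recycled) giving each regulator's class,
#'   `"TF"` or `"cofactor"`.
#' @return Object of class `TFTargetMap`.
#' @export
tf_target_map <- function(targets, class = "TF") {
  if (length(targets)) {
    if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
      stop("every regulator needs a name", call. = FALSE)
    }
    class <- rep_len(class, length(targets))
    if (!all(class %in% c("TF", "cofactor"))) {
      stop("regulator class must be 'TF' or 'cofactor'", call. = FALSE)
    }
    key <- paste(class, names(targets))
    if (anyDuplicated(key)) {
      stop("duplicate regulator within a class: ",
           paste(unique(names(targets)[duplicated(key)]), collapse = ", "),
           call. = FALSE)
    }
    targets <- lapply(targets, function(s) unique(as.character(s)))
    if (any(lengths(targets) == 0)) {
      stop("regulator(s) with empty target set: ",
           paste(names(targets)[lengths(targets) == 0], collapse = ", "),
           call. = FALSE)
    }
  } else {
    class <- character(0)
  }
  structure(list(targets = targets,
                 class = stats::setNames(class, names(targets))),
            class = "TFTargetMap")
}

#' @export
print.TFTargetMap <- function(x, ...) {
  cat(sprintf("TFTargetMap: %d regulators (%d TF, %d cofactor)\n",
              length(x$targets), sum(x$class == "TF"),
              sum(x$class == "cofactor")))
  invisible(x)
}
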