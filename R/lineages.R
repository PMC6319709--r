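#' Assign individuals or populations to lineages from admixture Q-vectors
#'
#' An individual is assigned to the cluster with the largest admixture
#' proportion when that proportion exceeds `threshold`; otherwise it is
#' labelled `"admixed"`.  Population-level assignment applies the same rule
#' to the population's mean Q-vector.
#'
#' @param q data frame or matrix of assignment probabilities, one row per
#'   individual (or population) and one column per cluster; column names
#'   become lineage labels (default `Eff1..EffK`).  An optional `id` /
#'   first non-numeric column is used as the row identifier.
#' @param threshold assignment threshold on the maximum Q (default 0.7).
#' @param population optional vector of population ids (same length as
#'   rows) enabling population-level assignment via mean Q-vectors.
#' @return data frame with `id`, the Q columns, and `lineage`; when
#'   `population` is given, attribute `"population_assignment"` holds the
#'   per-population table.
#' @examples
#' q <- data.frame(Eff1 = c(0.975, 0.5), Eff2 = c(0.022, 0.3),
#'                 Eff3 = c(0.003, 0.2))
#' assign_lineages(q)$lineage   # "Eff1", "admixed"
#' @export
assign_lineages <- function(q, threshold = 0.7, population = NULL) {
  q <- as.data.frame(q)
  num <- vapply(q, is.numeric, logical(1))
  id <- if (all(num)) rownames(q) %||% as.character(seq_len(nrow(q)))
        else as.character(q[[which(!num)[1]]])
  Q <- as.matrix(q[num])
  if (ncol(Q) < 2L) stop("need >= 2 cluster columns")
  if (is.null(colnames(Q)) || !all(nzchar(colnames(Q))))
    colnames(Q) <- paste0("Eff", seq_len(ncol(Q)))
  if (any(Q < 0 | Q > 1)) stop("Q values must lie in [0, 1]")
  s <- rowSums(Q)
  if (any(s < 0.95 | s > 1.05))
    stop("Q-vectors must sum to ~1; offending rows: ",
         paste(utils::head(which(s < 0.95 | s > 1.05), 5), collapse = ", "))
  call_one <- function(m) {
    j <- max.col(m, ties.method = "first")
    ifelse(m[cbind(seq_len(nrow(m)), j)] > threshold,
           colnames(m)[j], "admixed")
  }
  out <- data.frame(id = id, Q, lineage = call_one(Q),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(population)) {
    stopifnot(length(population) == nrow(Q))
    mq <- rowsum(Q, population)
    mq <- mq / as.vector(table(population)[rownames(mq)])
    mq <- mq[unique(population), , drop = FALSE]
    pa <- data.frame(population_id = rownames(mq), mq,
                     lineage = call_one(mq),
                     stringsAsFactors = FALSE, check.names = FALSE,
                     row.names = NULL)
    attr(out, "population_assignment") <- pa
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
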