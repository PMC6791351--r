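#' Random missing taxa (rMT)
#'
#' Each tip is missing independently with probability `p`, so the
#' realised number of missing tips is Binomial(n, p): at p = 0.5 on a
#' 600-tip tree the missing fraction typically ranges over roughly
#' 0.43-0.57 across replicates.
#'
#' @param tips Character vector of tip labels.
#' @param p Per-tip missingness probability, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Named integer vector of sampling status (0 = missing,
#'   1 = sampled).
#' @export
sample_missing_random <- function(tips, p, seed = NULL) {
  stopifnot(p >= 0, p < 1)
  if (!is.null(seed)) set.seed(seed)
  status <- as.integer(stats::runif(length(tips)) >= p)
  stats::setNames(status, tips)
}

#' Phylogenetically clumped missing taxa (cluMT)
#'
#' Threshold model: the tips with the lowest `round(p * n)` values of a
#' Brownian liability are missing. Because the liability has phylogenetic
#' signal, missing tips form clades-like clumps; the Fritz-Purvis D of the
#' resulting status is near 0. Deterministic given the liability (ties,
#' measure-zero for continuous liabilities, break by tip-label order).
#'
#' @param liability Named numeric vector of tip liabilities.
#' @param p Fraction of tips to drop, in `(0, 1)`.
#' @return Named integer sampling status over the same tips.
#' @export
sample_missing_clumped <- function(liability, p) {
  stopifnot(p > 0, p < 1)
  n <- length(liability)
  n_drop <- round(p * n)
  if (n - n_drop < 2L)
    stop("clumped missingness would leave fewer than 2 tips", call. = FALSE)
  ord <- order(liability, names(liability))
  status <- rep.int(1L, n)
  status[ord[seq_len(n_drop)]] <- 0L
  stats::setNames(status, names(liability))
}

#' Sampling weights for trait-correlated missingness
#'
#' For each tip, the weight of being drawn as missing is
#' `w = t / sum(T) - min(T) / sum(T)`, making the missingness probability
#' linearly proportional to the trait value; the tip with the minimum
#' trait gets weight exactly 0 and so is always sampled.
#'
#' @param trait Named numeric vector of tip trait values (not all equal;
#'   non-zero sum).
#' @return Named numeric weight vector.
#' @export
correlated_weights <- function(trait) {
  stopifnot(length(trait) >= 2)
  s <- sum(trait)
  if (s == 0) stop("trait values sum to zero; weights undefined", call. = FALSE)
  if (diff(range(trait)) == 0)
    stop("all trait values equal; weights are all zero", call. = FALSE)
  trait / s - min(trait) / s
}

#' Trait-correlated missing taxa (corMT)
#'
#' Marks exactly `round(p * n)` tips missing by sequential weighted draws
#' without replacement with probability proportional to
#' [correlated_weights()] (renormalised after each draw) — the semantics
#' of weighted integer sampling without replacement. Zero-weight tips
#' (the minimum-trait tip) are never missing.
#'
#' @param trait Named numeric vector of tip trait values.
#' @param p Fraction of tips to drop, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Named integer sampling status.
#' @export
sample_missing_correlated <- function(trait, p, seed = NULL) {
  stopifnot(p >= 0, p < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(trait)
  n_drop <- round(p * n)
  status <- stats::setNames(rep.int(1L, n), names(trait))
  if (n_drop == 0L) return(status)
  w <- correlated_weights(trait)
  if (n_drop > sum(w > 0))
    stop("requested missing count exceeds tips with positive weight",
         call. = FALSE)
  drop_idx <- sample.int(n, size = n_drop, replace = FALSE, prob = w)
  status[drop_idx] <- 0L
  status
}

#' Prune a tree and trait vector according to sampling status
#'
#' @param tree A `phylo` object.
#' @param trait Named numeric vector over the tree's tips.
#' @param status Named integer sampling status (0 = missing, 1 = sampled)
#'   over the same tips.
#' @return List with elements `tree` (pruned) and `trait` (restricted to
#'   sampled tips).
#' @export
apply_missingness <- function(tree, trait, status) {
  if (!setequal(names(status), tree$tip.label) ||
      !setequal(names(trait), tree$tip.label))
    stop("trait/status labels must match the tree's tips", call. = FALSE)
  drop <- names(status)[status == 0L]
  pruned <- prune_tips(tree, drop)
  list(tree = pruned, trait = trait[pruned$tip.label])
}

#' Write / read sampling status as TSV
#'
#' Two-column tab-separated files `(tip_label, status)`; traits use the
#' same layout with a `value` column.
#'
#' @param status Named integer status vector.
#' @param path File path.
#' @return `read_status_tsv` returns a named integer vector;
#'   `write_status_tsv` returns `path` invisibly.
#' @export
write_status_tsv <- function(status, path) {
  utils::write.table(
    data.frame(tip_label = names(status), status = as.integer(status)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_status_tsv
#' @export
read_status_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.integer(d[[2]]), as.character(d[[1]]))
}

#' @rdname write_status_tsv
#' @param trait Named numeric trait vector.
#' @export
write_trait_tsv <- function(trait, path) {
  utils::write.table(
    data.frame(tip_label = names(trait), value = as.numeric(trait)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_status_tsv
#' @export
read_trait_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2]]), as.character(d[[1]]))
}
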