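#' Draw random ligand pairs for threshold calibration
#'
#' Samples sets of random (non-self) ligand pairs from a library, the
#' background against which the minimum cognate-similarity threshold is
#' calibrated: the similarity distribution of randomly paired molecules
#' estimates the score a noncognate pair can reach by chance. Pairs are
#' drawn uniformly, without replacement within a pair, with replacement
#' across pairs.
#'
#' @param ligands A list of `molecule` objects (length >= 2).
#' @param n_pairs Pairs per set.
#' @param n_sets Number of replicate sets.
#' @param seed Integer seed; identical seeds give identical pair lists.
#' @return A list of `n_sets` sets; each set is a list of 2-element lists
#'   of molecules.
#' @export
sample_random_pairs <- function(ligands, n_pairs = 2000, n_sets = 5,
                                seed = 1L) {
  if (length(ligands) < 2) {
    stop("need at least 2 ligands to form random pairs")
  }
  stopifnot(n_pairs >= 1, n_sets >= 1)
  n <- length(ligands)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  lapply(seq_len(n_sets), function(s) {
    lapply(seq_len(n_pairs), function(p) {
      ij <- sample.int(n, 2, replace = FALSE)
      list(ligands[[ij[1]]], ligands[[ij[2]]])
    })
  })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Calibrate the minimum cognate-similarity threshold from random pairs
#'
#' Scores every pair in every set with [parity_score()], takes the
#' configured percentile of each set (linear interpolation between order
#' statistics), and places the threshold a margin above the mean percentile,
#' rounded at the configured precision. With the default additive margin of
#' 0.10 and a mean 95th percentile of 0.29, the threshold is 0.4 — the
#' score below which a match is no better than a typical random ligand
#' pairing.
#'
#' @param sets Either sets of molecule pairs as returned by
#'   [sample_random_pairs()], or a list of numeric score vectors (already
#'   computed similarities).
#' @param percentile Percentile per set, default 95.
#' @param margin Margin above the mean percentile, default 0.10.
#' @param margin_type `"additive"` (threshold = mean + margin, default) or
#'   `"multiplicative"` (threshold = mean * (1 + margin)).
#' @param digits Decimal places the threshold is rounded to, default 1.
#' @param timeout_s Per-pair similarity timeout, seconds.
#' @return A `calibration_result`: list with `per_set_p95`, `mean_p95`,
#'   `sd_p95`, `threshold`, `percentile`, `margin`, `margin_type`.
#' @export
calibrate_threshold <- function(sets, percentile = 95, margin = 0.10,
                                margin_type = c("additive", "multiplicative"),
                                digits = 1, timeout_s = 10) {
  margin_type <- match.arg(margin_type)
  if (length(sets) == 0) stop("no calibration sets supplied")
  score_sets <- lapply(sets, function(s) {
    if (is.numeric(s)) {
      if (length(s) == 0) stop("empty calibration set")
      return(s)
    }
    if (length(s) == 0) stop("empty calibration set")
    vapply(s, function(pair) {
      parity_score(pair[[1]], pair[[2]], timeout_s = timeout_s)$score
    }, numeric(1))
  })
  p <- vapply(score_sets, stats::quantile, numeric(1),
              probs = percentile / 100, names = FALSE, type = 7)
  mean_p <- mean(p)
  thr <- switch(margin_type,
                additive = mean_p + margin,
                multiplicative = mean_p * (1 + margin))
  structure(
    list(per_set_p95 = p, mean_p95 = mean_p,
         sd_p95 = if (length(p) > 1) stats::sd(p) else NA_real_,
         threshold = round(thr, digits),
         percentile = percentile, margin = margin,
         margin_type = margin_type),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration> p%g per set: %s\n  mean = %.3f (sd %.3f) -> threshold %.2g (%s margin %.2g)\n",
    x$percentile, paste(sprintf("%.3f", x$per_set_p95), collapse = ", "),
    x$mean_p95, x$sd_p95, x$threshold, x$margin_type, x$margin))
  invisible(x)
}
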