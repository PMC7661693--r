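#' Quadratic weighted kappa for ordinal reader agreement
#'
#' Chance-corrected agreement for paired ordinal ratings with squared
#' disagreement weights: kappa = 1 - sum(w O) / sum(w E), where O is the
#' observed joint proportion matrix, E the outer product of the two raters'
#' marginals, and w_ij = (i - j)^2 / (k - 1)^2. When both raters are
#' constant and identical the expected weighted disagreement is zero and no
#' plausible kappa exists; the result is then flagged `degenerate` with an
#' `NA` estimate rather than a number.
#'
#' @param ratings_a,ratings_b Equal-length vectors of ratings from the two
#'   readers.
#' @param categories Ordered category levels (default the 0-3 image-quality
#'   scale).
#' @return An object of class `mra_kappa`: `kappa`, `n`, `observed`,
#'   `expected`, `weights`, `degenerate`, `interpretation`.
#' @examples
#' quadratic_weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3))$kappa # 1
#' @export
quadratic_weighted_kappa <- function(ratings_a, ratings_b, categories = 0:3) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 1L) {
    stop("ratings must be paired vectors of equal length >= 1", call. = FALSE)
  }
  if (!all(ratings_a %in% categories) || !all(ratings_b %in% categories)) {
    stop("ratings outside the category set", call. = FALSE)
  }
  k <- length(categories)
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  O <- table(fa, fb) / length(ratings_a)
  O <- matrix(as.numeric(O), k, k)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(k) - 1L
  W <- outer(idx, idx, function(i, j) (i - j)^2 / (k - 1)^2)
  ewd <- sum(W * E)
  degenerate <- ewd == 0
  kappa <- if (degenerate) NA_real_ else 1 - sum(W * O) / ewd
  structure(list(kappa = kappa, n = length(ratings_a),
                 observed = O, expected = E, weights = W,
                 degenerate = degenerate,
                 interpretation = kappa_interpretation(kappa)),
            class = "mra_kappa")
}

#' Verbal interpretation band of a kappa value
#'
#' Standard banding: <= 0 poor, 0.01-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00 excellent.
#'
#' @param kappa Numeric kappa (NA allowed).
#' @return Character band label.
#' @export
kappa_interpretation <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) return("poor")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("good")
  "excellent"
}

#' @export
print.mra_kappa <- function(x, ...) {
  if (x$degenerate) {
    cat("<mra_kappa> undefined: extreme margins (zero expected disagreement)\n")
  } else {
    cat(sprintf("<mra_kappa> %.3f (%s agreement), n = %d\n",
                x$kappa, x$interpretation, x$n))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname quadratic_weighted_kappa
#' @param x An `mra_kappa` object.
#' @param ... Unused.
#' @export
tidy.mra_kappa <- function(x, ...) {
  tibble::tibble(estimate = x$kappa, n = x$n,
                 degenerate = x$degenerate,
                 interpretation = x$interpretation)
}

#' @rdname quadratic_weighted_kappa
#' @export
glance.mra_kappa <- function(x, ...) tidy(x)

#' Summarise image-quality scores
#'
#' Grouped arithmetic means and sample SDs of 0-3 quality ratings, per
#' reconstruction method and table position plus an overall row per method.
#' Groups with a single rating get `sd_score = NA` (flagged by `n`).
#'
#' @param ratings Tibble with at least `method`, `station_label` and
#'   `score` columns (one row per rated segment per reader).
#' @return Tibble with `method`, `station_label` (including `"overall"`),
#'   `n`, `mean_score`, `sd_score`.
#' @export
summarize_scores <- function(ratings) {
  stopifnot(all(c("method", "station_label", "score") %in% names(ratings)))
  if (!all(ratings$score %in% 0:3)) {
    stop("scores must lie on the 0-3 scale", call. = FALSE)
  }
  one <- function(tbl, station) {
    tbl |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_score = mean(.data$score),
                       sd_score = if (dplyr::n() > 1) stats::sd(.data$score) else NA_real_,
                       .groups = "drop") |>
      dplyr::mutate(station_label = station, .after = "method")
  }
  per_station <- ratings |>
    dplyr::group_by(.data$station_label) |>
    dplyr::group_map(~ one(.x, .y$station_label)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_station, one(ratings, "overall"))
}
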