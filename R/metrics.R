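#' Association metrics over sentence/document contingency counts
#'
#' Eight edge-weight metrics used to score the association between two
#' entities from their co-occurrence sufficient statistics. All statistical
#' metrics are computed on sentence-level counts; only `doc_count` reads the
#' document-level counts. With `P(a) = n_a/N`, `P(b) = n_b/N`,
#' `P(ab) = n_ab/N` (`N` = total sentences) and the 2x2 table
#' `O11 = n_ab`, `O12 = n_a - n_ab`, `O21 = n_b - n_ab`,
#' `O22 = N - n_a - n_b + n_ab`:
#'
#' * `count`: `n_ab`
#' * `doc_count`: `d_ab`
#' * `jaccard`: `n_ab / (n_a + n_b - n_ab)`
#' * `scp`: `P(ab)^2 / (P(a) P(b))` (symmetric conditional probability)
#' * `npmi`: `ln(P(ab)/(P(a)P(b))) / (-ln P(ab))`, defined as 1 when
#'   `P(ab) = 1`
#' * `chi_squared`: `N (O11 O22 - O12 O21)^2 / (n_a n_b (N-n_a) (N-n_b))`
#' * `t_test`: `(P(ab) - P(a)P(b)) / sqrt(P(ab)(1-P(ab))/N)` (Bernoulli
#'   variance, collocation-statistics convention)
#' * `llr`: `2 * sum(Oij * ln(Oij/Eij))` with the convention `0 ln 0 = 0`,
#'   `Eij` the expected counts under independence
#'
#' Natural logarithms throughout. Degenerate margins (an entity present in
#' every sentence, or a pair present in every sentence) force exact
#' independence or perfect association; the 0/0 limits are defined as 0
#' (`chi_squared`, `t_test`) and 1 (`npmi` at `P(ab) = 1`) so valid counts
#' never raise.
#'
#' @param name metric name, one of [lbd_metrics()]
#' @param counts a `contingency_counts` object or a list/data.frame with
#'   fields `n_ab`, `n_a`, `n_b`, `n_sent` and (for `doc_count`) `d_ab`.
#'   Vectorized: fields may be equal-length vectors.
#' @return numeric vector of weights
#' @examples
#' cc <- contingency_counts(n_ab = 5, n_a = 10, n_b = 20, n_sent = 100)
#' compute_metric("jaccard", cc)  # 0.2
#' compute_metric("scp", cc)      # 0.125
#' @export
compute_metric <- function(name, counts) {
  fn <- .metric_registry[[match.arg(name, lbd_metrics())]]
  # promote to double up front: the chi-squared / llr closed forms multiply
  # counts whose product overflows 32-bit integers at corpus scale
  num <- lapply(counts[c("n_ab", "n_a", "n_b", "n_sent", "d_ab", "d_a",
                         "d_b", "n_doc")],
                function(x) if (is.null(x)) NA_real_ else as.numeric(x))
  fn(num)
}

#' Registered metric names
#'
#' @return character vector of the metric names accepted by
#'   [compute_metric()] and the query functions, in registry order.
#' @export
lbd_metrics <- function() names(.metric_registry)

#' Contingency counts for one entity pair
#'
#' Sufficient statistics feeding every association metric: sentence counts
#' for the pair and each entity, document analogues, and corpus totals.
#'
#' @param n_ab,n_a,n_b sentence co-occurrence / marginal counts
#' @param n_sent total sentences in the corpus slice
#' @param d_ab,d_a,d_b,n_doc document-level analogues (optional; `NA` when
#'   unused)
#' @return a `contingency_counts` list
#' @export
contingency_counts <- function(n_ab, n_a, n_b, n_sent,
                               d_ab = NA_real_, d_a = NA_real_,
                               d_b = NA_real_, n_doc = NA_real_) {
  bad <- n_ab < 1 | n_ab > pmin(n_a, n_b) | (n_a + n_b - n_ab) > n_sent
  if (any(bad, na.rm = TRUE))
    stop("invalid contingency counts: need 0 < n_ab <= min(n_a, n_b) and ",
         "n_a + n_b - n_ab <= n_sent")
  structure(list(n_ab = as.numeric(n_ab), n_a = as.numeric(n_a),
                 n_b = as.numeric(n_b), n_sent = as.numeric(n_sent),
                 d_ab = as.numeric(d_ab), d_a = as.numeric(d_a),
                 d_b = as.numeric(d_b), n_doc = as.numeric(n_doc)),
            class = "contingency_counts")
}

# x * ln(x) with the 0 ln 0 = 0 convention, elementwise
.xlogx_ratio <- function(o, e) {
  out <- numeric(length(o))
  nz <- o > 0
  out[nz] <- o[nz] * log(o[nz] / e[nz])
  out
}

.metric_registry <- list(
  count = function(c) c$n_ab,
  doc_count = function(c) c$d_ab,
  jaccard = function(c) c$n_ab / (c$n_a + c$n_b - c$n_ab),
  scp = function(c) {
    (c$n_ab / c$n_sent)^2 / ((c$n_a / c$n_sent) * (c$n_b / c$n_sent))
  },
  npmi = function(c) {
    pab <- c$n_ab / c$n_sent
    pa <- c$n_a / c$n_sent
    pb <- c$n_b / c$n_sent
    ifelse(pab >= 1, 1, log(pab / (pa * pb)) / (-log(pab)))
  },
  chi_squared = function(c) {
    N <- c$n_sent
    o11 <- c$n_ab; o12 <- c$n_a - c$n_ab
    o21 <- c$n_b - c$n_ab; o22 <- N - c$n_a - c$n_b + c$n_ab
    den <- c$n_a * c$n_b * (N - c$n_a) * (N - c$n_b)
    num <- N * (o11 * o22 - o12 * o21)^2
    ifelse(den == 0, 0, num / den)
  },
  t_test = function(c) {
    pab <- c$n_ab / c$n_sent
    pa <- c$n_a / c$n_sent
    pb <- c$n_b / c$n_sent
    v <- pab * (1 - pab) / c$n_sent
    ifelse(v == 0, 0, (pab - pa * pb) / sqrt(v))
  },
  llr = function(c) {
    N <- c$n_sent
    o11 <- c$n_ab; o12 <- c$n_a - c$n_ab
    o21 <- c$n_b - c$n_ab; o22 <- N - c$n_a - c$n_b + c$n_ab
    e11 <- c$n_a * c$n_b / N
    e12 <- c$n_a * (N - c$n_b) / N
    e21 <- (N - c$n_a) * c$n_b / N
    e22 <- (N - c$n_a) * (N - c$n_b) / N
    2 * (.xlogx_ratio(o11, e11) + .xlogx_ratio(o12, e12) +
           .xlogx_ratio(o21, e21) + .xlogx_ratio(o22, e22))
  }
)
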