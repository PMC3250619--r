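#' Tidy a criterion series
#'
#' @param x A `criterion_series`.
#' @param ... Unused.
#' @return Tibble with `method`, `k`, `score`, `selected`, plus any
#'   auxiliary per-k columns the criterion carries (e.g. `E_R2`, `s`).
#' @method tidy criterion_series
#' @export
tidy.criterion_series <- function(x, ...) {
  out <- tibble::tibble(method = x$method, k = x$k_values, score = x$scores,
                        selected = x$k_values == x$k_hat)
  if (!is.null(x$aux))
    out <- dplyr::left_join(out, x$aux, by = "k")
  out
}

#' @method glance criterion_series
#' @export
glance.criterion_series <- function(x, ...) {
  tibble::tibble(method = x$method, k_hat = as.integer(x$k_hat),
                 flag = x$flag)
}

#' Tidy a gDGC result: per-gene group assignment
#'
#' @param x A `gdgc_result`.
#' @param ... Unused.
#' @return Tibble with `gene`, `group`, `letter`.
#' @method tidy gdgc_result
#' @export
tidy.gdgc_result <- function(x, ...) {
  tibble::tibble(gene = names(x$labels), group = as.integer(x$labels),
                 letter = unname(x$letters))
}

#' @method glance gdgc_result
#' @export
glance.gdgc_result <- function(x, ...) {
  tibble::tibble(Q_observed = x$Q_observed, Q_critical = x$Q_critical,
                 alpha = x$alpha, reject = x$reject,
                 n_groups = as.integer(x$k), linkage = x$linkage,
                 B_null = x$null$B_null)
}

#' Tidy a multi-method estimate: long table of criterion scores
#'
#' @param x A `k_estimate` from [estimate_k()].
#' @param ... Unused.
#' @method tidy k_estimate
#' @export
tidy.k_estimate <- function(x, ...) {
  crit <- purrr::keep(x$series, inherits, "criterion_series")
  dplyr::bind_rows(purrr::map(crit, tidy))
}

#' @method glance k_estimate
#' @export
glance.k_estimate <- function(x, ...) x$summary

#' Tidy a null distribution of the root distance
#'
#' @param x A `null_q`.
#' @param ... Unused.
#' @return Tibble of the sorted samples with their empirical probabilities.
#' @method tidy null_q
#' @export
tidy.null_q <- function(x, ...) {
  tibble::tibble(Q = x$samples,
                 prob = seq_along(x$samples) / length(x$samples))
}

#' @method glance null_q
#' @export
glance.null_q <- function(x, ...) {
  tibble::tibble(B_null = x$B_null, n = x$n, p = x$p, N = x$N,
                 linkage = x$linkage,
                 Q_90 = critical_value(x, 0.10),
                 Q_95 = critical_value(x, 0.05),
                 Q_99 = critical_value(x, 0.01))
}
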