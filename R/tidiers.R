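#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a consensus extraction result
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `C_k`, `n_members`.
#' @export
tidy.consensus_result <- function(x, ...) {
  x$cluster_stability |>
    dplyr::mutate(n_members = as.integer(table(x$labels)[as.character(.data$cluster)]))
}

#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(k = x$k, C_mean = x$C_mean, C_min = x$C_min, stable = x$stable)
}

#' Tidy a rank selection: the per-rank diagnostics table
#'
#' @param x A `rank_selection`.
#' @param ... Unused.
#' @export
tidy.rank_selection <- function(x, ...) {
  x$diagnostics |>
    dplyr::mutate(chosen = .data$k == x$chosen_k)
}

#' @export
glance.rank_selection <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, stable_selection = x$stable_selection)
}

#' Tidy an extraction result: the consensus signature profiles
#'
#' @param x An `extraction_result`.
#' @param ... Unused.
#' @export
tidy.extraction_result <- function(x, ...) {
  tidy(x$signatures)
}

#' @export
glance.extraction_result <- function(x, ...) {
  tibble::tibble(k = nrow(x$signatures),
                 C_mean = x$consensus$C_mean,
                 C_min = x$consensus$C_min,
                 stable_selection = x$selection$stable_selection)
}

#' Tidy a scenario evaluation: per-replicate outcomes
#'
#' @param x An `extraction_evaluation`.
#' @param ... Unused.
#' @export
tidy.extraction_evaluation <- function(x, ...) {
  x$per_replicate
}

#' @export
glance.extraction_evaluation <- function(x, ...) {
  tibble::tibble(F = x$F,
                 mse_median = x$mse$median, mse_q1 = x$mse$q1, mse_q3 = x$mse$q3,
                 C_mean_median = x$stability$C_mean,
                 C_min_median = x$stability$C_min)
}

#' Tidy an archetype model: the alpha coefficients in long form
#'
#' @param x An `archetype_model`.
#' @param ... Unused.
#' @return Tibble with columns `signature`, `archetype`, `alpha`.
#' @export
tidy.archetype_model <- function(x, ...) {
  tibble::as_tibble(as.table(x$alpha), .name_repair = "minimal") |>
    stats::setNames(c("signature", "archetype", "alpha"))
}

#' @export
glance.archetype_model <- function(x, ...) {
  tibble::tibble(r = x$r, sse = x$sse,
                 explained_variance = x$explained_variance,
                 converged = x$converged, iterations = x$iterations)
}
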