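#' Cost per QALY
#'
#' @param total_cost Total discounted cost, USD. Vectorised.
#' @param total_qaly Total discounted QALYs; strictly positive.
#' @return Cost per QALY in USD, at full precision; report with
#'   [round_half_up()].
#' @examples
#' round_half_up(cost_per_qaly(159993.30, 1.81)) # 88394.09
#' @export
cost_per_qaly <- function(total_cost, total_qaly) {
  if (any(!is.finite(total_qaly)) || any(total_qaly <= 0)) {
    abort_invalid("`total_qaly` must be positive.")
  }
  total_cost / total_qaly
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `ICER = (cost_i - cost_c) / (qaly_i - qaly_c)` for an intervention `i`
#' against a comparator `c`. A negative ICER arises when one strategy is
#' cheaper and more effective (dominance); it is flagged rather than
#' interpreted as a price. When the QALY difference is zero the ICER is
#' undefined and returned as `NA` with `defined = FALSE` — no infinity
#' arithmetic.
#'
#' @param intervention,comparator One-row data frames (or named lists) with
#'   `total_cost` and `total_qaly`.
#' @return Tibble with `incremental_cost`, `incremental_qaly`, `icer`,
#'   `defined`, and `note` (`""`, `"undefined"` or
#'   `"negative: dominance, not a price"`).
#' @examples
#' icer(list(total_cost = 157748.27, total_qaly = 1.91),
#'      list(total_cost = 140920.25, total_qaly = 1.87))
#' @export
icer <- function(intervention, comparator) {
  gi <- as.list(intervention)
  gc_ <- as.list(comparator)
  d_cost <- gi$total_cost - gc_$total_cost
  d_qaly <- gi$total_qaly - gc_$total_qaly
  if (abs(d_qaly) < .Machine$double.eps * 4) {
    return(tibble(incremental_cost = d_cost, incremental_qaly = 0,
                  icer = NA_real_, defined = FALSE, note = "undefined"))
  }
  value <- d_cost / d_qaly
  tibble(incremental_cost = d_cost, incremental_qaly = d_qaly,
         icer = value, defined = TRUE,
         note = if (value < 0) "negative: dominance, not a price" else "")
}

#' Classify dominance and build the efficiency frontier
#'
#' A strategy is strongly dominated when another costs no more and yields
#' no fewer QALYs, with at least one strict inequality; identical
#' strategies therefore do not dominate each other. The efficiency frontier
#' is the nondominated set ordered by increasing QALY (ties broken by lower
#' cost, then name); strategies whose frontier ICER is not increasing are
#' additionally flagged as extendedly (weakly) dominated, reported
#' separately because base-case conclusions use strong dominance only.
#'
#' @param results Data frame with columns `name`, `total_cost`,
#'   `total_qaly` (one row per strategy; at least one).
#' @return A `cea_result` tibble: the input plus `cost_per_qaly`,
#'   `dominated`, `dominated_by` (comma-separated list of dominating
#'   strategies), `extendedly_dominated`, `on_frontier`.
#'   The ordered frontier with pairwise ICERs is attached as the
#'   `"frontier"` attribute and returned by [frontier()].
#' @export
classify_dominance <- function(results) {
  req <- c("name", "total_cost", "total_qaly")
  if (!all(req %in% names(results))) {
    abort_invalid(paste0("`results` needs columns: ",
                         paste(req, collapse = ", "), "."))
  }
  res <- as_tibble(results)
  if (anyDuplicated(res$name)) {
    abort_invalid("strategy names must be unique.")
  }
  n <- nrow(res)
  dominated_by <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    doms <- character(0)
    for (j in seq_len(n)) {
      if (i == j) next
      better_cost <- res$total_cost[j] <= res$total_cost[i]
      better_qaly <- res$total_qaly[j] >= res$total_qaly[i]
      strict <- res$total_cost[j] < res$total_cost[i] ||
        res$total_qaly[j] > res$total_qaly[i]
      if (better_cost && better_qaly && strict) doms <- c(doms, res$name[j])
    }
    if (length(doms)) dominated_by[i] <- paste(doms, collapse = ",")
  }
  res$cost_per_qaly <- cost_per_qaly(res$total_cost, res$total_qaly)
  res$dominated <- !is.na(dominated_by)
  res$dominated_by <- dominated_by

  # frontier: nondominated, by increasing QALY (lower cost, then name, on ties)
  front <- res |>
    filter(!.data$dominated) |>
    arrange(.data$total_qaly, .data$total_cost, .data$name)

  # extended dominance: sequential frontier ICERs must increase
  ext <- character(0)
  repeat {
    if (nrow(front) < 3L) break
    ic <- c(NA_real_, map_dbl(2:nrow(front), function(k) {
      icer(front[k, ], front[k - 1L, ])$icer
    }))
    bad <- which(diff(ic[-1L]) <= 0)  # ICER fails to increase at k+1 vs k
    if (!length(bad)) break
    drop_name <- front$name[bad[1L] + 1L]
    ext <- c(ext, drop_name)
    front <- front[front$name != drop_name, ]
  }
  res$extendedly_dominated <- res$name %in% ext
  res$on_frontier <- !res$dominated & !res$extendedly_dominated

  front <- res |>
    filter(.data$on_frontier) |>
    arrange(.data$total_qaly, .data$total_cost, .data$name)
  if (nrow(front)) {
    front$icer_vs_previous <- c(NA_real_, map_dbl(seq_len(nrow(front))[-1L],
      function(k) icer(front[k, ], front[k - 1L, ])$icer))
  }
  structure(res, class = c("cea_result", class(res)), frontier = front)
}

#' Efficiency frontier of a dominance classification
#'
#' @param x A `cea_result` from [classify_dominance()].
#' @return The frontier tibble (strategies by increasing QALY with
#'   `icer_vs_previous`).
#' @export
frontier <- function(x) {
  stopifnot(inherits(x, "cea_result"))
  attr(x, "frontier")
}

#' @export
tidy.cea_result <- function(x, ...) as_tibble(unclass(x))

#' One-row summary of a dominance classification
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return Tibble with strategy counts and the preferred (lowest
#'   cost-per-QALY nondominated) strategy.
#' @export
glance.cea_result <- function(x, ...) {
  nd <- x[!x$dominated, ]
  tibble(n_strategies = nrow(x),
         n_dominated = sum(x$dominated),
         n_frontier = sum(x$on_frontier),
         preferred = nd$name[which.min(nd$cost_per_qaly)])
}

#' Cost-effectiveness plane
#'
#' @param object A `cea_result`.
#' @param ... Unused.
#' @return A ggplot: QALYs against cost, dominated strategies marked, the
#'   efficiency frontier drawn through the nondominated set.
#' @export
autoplot.cea_result <- function(object, ...) {
  df <- tidy(object)
  front <- frontier(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_qaly, y = .data$total_cost)) +
    ggplot2::geom_line(data = front, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$dominated), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1,
                       size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "QALYs", y = "Cost (USD)", shape = "Dominated")
}

#' Willingness-to-pay decision for an ICER
#'
#' @param icer_value ICER in USD/QALY; `NA` for undefined.
#' @param threshold Willingness-to-pay threshold, USD/QALY (base case
#'   20,301, triple the Chinese per-capita GDP); positive.
#' @return `"acceptable"` if the ICER is defined and at most the threshold
#'   (negative ICERs from dominant interventions are acceptable),
#'   `"not_acceptable"` above it, `"deferred_to_dominance"` when undefined.
#' @examples
#' wtp_decision(420700.50, 20301) # "not_acceptable"
#' @export
wtp_decision <- function(icer_value, threshold = 20301) {
  assert_scalar_number(threshold, "threshold", min = 1e-12)
  if (is.na(icer_value)) return("deferred_to_dominance")
  if (icer_value <= threshold) "acceptable" else "not_acceptable"
}
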