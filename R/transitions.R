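#' Convert a median time-to-event into a monthly transition probability
#'
#' Under an exponential (memoryless) time-to-event assumption with monthly
#' model cycles, a median of `m` months implies a constant per-cycle
#' transition probability `P = 1 - 0.5^(1/m)`, equivalently
#' `P = 1 - exp(-R)` with monthly rate `R = -log(0.5)/m`. After `m` cycles a
#' cohort exposed to `P` each cycle retains exactly half its members.
#'
#' @param median_months Median time to event in months; strictly positive.
#'   Vectorised.
#' @return Per-cycle transition probability in (0, 1).
#' @examples
#' median_to_monthly_prob(1)    # 0.5: half transition each cycle
#' median_to_monthly_prob(11.3) # monthly progression probability, median
#'                              # PFS 11.3 months
#' @export
median_to_monthly_prob <- function(median_months) {
  if (!is.numeric(median_months) || length(median_months) < 1L ||
      anyNA(median_months) || any(median_months <= 0)) {
    abort_invalid("`median_months` must be positive.")
  }
  1 - 0.5^(1 / median_months)
}

#' Assemble the three-state monthly transition matrix
#'
#' Health states are stable disease (SD), progressive disease (PD) and death
#' (absorbing). Two structures are supported:
#'
#' * `"progression_required"` (default): deaths occur only from PD. The SD
#'   exit probability comes from median PFS; the PD-to-death probability
#'   from the post-progression median `median_os - median_pfs`. With only
#'   two published medians this keeps the overall-survival decomposition
#'   identifiable.
#' * `"direct_death"`: SD patients may also die without recorded
#'   progression. The SD exit hazard is split so that total time to death
#'   still reflects `median_os`; the SD-to-death probability is derived
#'   from `median_os` directly and the SD-to-PD probability from
#'   `median_pfs`, capped so the row sums stay valid.
#'
#' @param median_pfs Median progression-free survival, months.
#' @param median_os Median overall survival, months; must exceed
#'   `median_pfs`.
#' @param structure `"progression_required"` or `"direct_death"`.
#' @return A `transition_matrix` object: a named list with elements
#'   `p_sd_to_pd`, `p_sd_to_dead`, `p_pd_to_dead` and the `structure` used.
#' @examples
#' build_transition_matrix(11.3, 31.2)
#' build_transition_matrix(1, 2) # both sub-medians of one cycle: 0.5 / 0.5
#' @export
build_transition_matrix <- function(median_pfs, median_os,
                                    structure = c("progression_required",
                                                  "direct_death")) {
  structure <- match.arg(structure)
  assert_scalar_number(median_pfs, "median_pfs", min = 1e-9)
  assert_scalar_number(median_os, "median_os", min = 1e-9)
  if (median_os <= median_pfs) {
    abort_invalid(sprintf(
      "`median_os` (%g) must exceed `median_pfs` (%g): post-progression time must be positive.",
      median_os, median_pfs))
  }
  p_pfs <- median_to_monthly_prob(median_pfs)
  p_post <- median_to_monthly_prob(median_os - median_pfs)
  if (structure == "progression_required") {
    out <- list(p_sd_to_pd = p_pfs, p_sd_to_dead = 0, p_pd_to_dead = p_post)
  } else {
    # direct-death variant: a share of the SD exit hazard goes straight to
    # death at the overall-survival rate; progression takes the remainder
    p_os <- median_to_monthly_prob(median_os)
    p_sd_pd <- max(p_pfs - p_os, 0)
    out <- list(p_sd_to_pd = p_sd_pd, p_sd_to_dead = p_os,
                p_pd_to_dead = p_post)
  }
  validate_transition_matrix(out)
  structure(c(out, list(structure = structure)),
            class = "transition_matrix")
}

validate_transition_matrix <- function(x) {
  for (nm in c("p_sd_to_pd", "p_sd_to_dead", "p_pd_to_dead")) {
    assert_scalar_number(x[[nm]], nm, min = 0, max = 1)
  }
  if (x$p_sd_to_pd + x$p_sd_to_dead > 1 + 1e-12) {
    abort_invalid("SD exit probabilities exceed 1.")
  }
  invisible(x)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Monthly transition matrix (", x$structure, ")\n", sep = "")
  cat(sprintf("  SD -> PD   %.6f\n", x$p_sd_to_pd))
  cat(sprintf("  SD -> dead %.6f\n", x$p_sd_to_dead))
  cat(sprintf("  PD -> dead %.6f\n", x$p_pd_to_dead))
  invisible(x)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) {
  m <- matrix(c(1 - x$p_sd_to_pd - x$p_sd_to_dead, x$p_sd_to_pd, x$p_sd_to_dead,
                0, 1 - x$p_pd_to_dead, x$p_pd_to_dead,
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("sd", "pd", "dead"), c("sd", "pd", "dead")))
  m
}
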