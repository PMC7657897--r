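#' Tidy an E-box survey
#'
#' @param x An `ebox_survey` from [compare_regions()].
#' @param what Which underlying table to return: the per-window `hits`,
#'   the `near_misses`, or the `pairs`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ebox_survey <- function(x, what = c("hits", "near_misses", "pairs"),
                             ...) {
  what <- match.arg(what)
  as_tibble(attr(x, what))
}

#' One-row summary of an E-box survey
#'
#' @param x An `ebox_survey`.
#' @param ... Unused.
#' @return A one-row tibble: regions scanned and motif/pair totals.
#' @export
glance.ebox_survey <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_generic = sum(x$n_generic, na.rm = TRUE),
    n_myod = sum(x$n_myod, na.rm = TRUE),
    n_exact_pairs = sum(x$n_exact_pairs),
    n_presumptive_pairs = sum(x$n_presumptive_pairs)
  )
}

#' Tidy CPS classification calls
#'
#' @param x A `cps_calls` tibble from [classify_cps()].
#' @param ... Unused.
#' @return The long per-residue state table the calls were derived from.
#' @export
tidy.cps_calls <- function(x, ...) {
  as_tibble(attr(x, "states"))
}

#' One-row summary of CPS classification calls
#'
#' @param x A `cps_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble with sequence and per-class counts.
#' @export
glance.cps_calls <- function(x, ...) {
  counts <- map_int(setNames(CPS_CLASSES, tolower(CPS_CLASSES)),
                    function(cl) sum(x$functional_class == cl))
  dplyr::bind_cols(tibble(n_sequences = nrow(x)), as_tibble(as.list(counts)))
}
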