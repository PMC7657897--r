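#' Track plot of an E-box survey
#'
#' One horizontal track per promoter region, with motif hits drawn as
#' segments (near-misses hollow) and paired sites underlaid as translucent
#' boxes. The x axis is the upstream distance from the TSS, so position 0
#' is the TSS and motifs read right to left along the genome.
#'
#' @param object An `ebox_survey` from [compare_regions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ebox_survey <- function(object, ...) {
  hits <- bind_rows(attr(object, "hits"), attr(object, "near_misses"))
  pairs <- attr(object, "pairs")
  lens <- setNames(object$region_length, object$seq_id)
  p <- ggplot2::ggplot()
  if (nrow(pairs) > 0L) {
    pairs <- mutate(pairs,
      up_distal = unname(lens[.data$seq_id]) - .data$first_start + 1L,
      up_proximal = unname(lens[.data$seq_id]) - .data$second_end + 1L
    )
    p <- p + ggplot2::geom_rect(
      data = pairs,
      ggplot2::aes(xmin = .data$up_proximal, xmax = .data$up_distal,
                   ymin = as.numeric(factor(.data$seq_id,
                                            levels = object$seq_id)) - 0.35,
                   ymax = as.numeric(factor(.data$seq_id,
                                            levels = object$seq_id)) + 0.35,
                   alpha = .data$category),
      fill = "steelblue"
    ) +
      ggplot2::scale_alpha_manual(
        values = c(exact = 0.35, presumptive = 0.15), name = "pair"
      )
  }
  if (nrow(hits) > 0L) {
    hits <- mutate(hits, kind = if_else(.data$mismatches > 0L,
                                        "near-miss", .data$label))
    p <- p + ggplot2::geom_segment(
      data = hits,
      ggplot2::aes(x = .data$upstream_proximal, xend = .data$upstream_distal,
                   y = factor(.data$seq_id, levels = object$seq_id),
                   yend = factor(.data$seq_id, levels = object$seq_id),
                   colour = .data$kind),
      linewidth = 4
    )
  }
  p +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "distance upstream of TSS (bp)", y = NULL,
                  colour = "motif") +
    ggplot2::theme_minimal()
}

#' Residue-state heat map of CPS classification calls
#'
#' Tiles the five diagnostic positions (catalytic triad plus the two
#' glutamine-binding residues) for every sequence, coloured by state and
#' annotated with the observed residue.
#'
#' @param object A `cps_calls` tibble from [classify_cps()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cps_calls <- function(object, ...) {
  states <- attr(object, "states")
  states$name <- factor(states$name,
                        levels = c("Cys", "His", "Glu", "Gln1", "Gln2"))
  ggplot2::ggplot(states,
                  ggplot2::aes(x = .data$name, y = .data$seq_id,
                               fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$observed), size = 3) +
    ggplot2::scale_fill_manual(values = c(match = "#4daf4a",
                                          divergent = "#e41a1c",
                                          gap = "grey70")) +
    ggplot2::labs(x = "diagnostic residue", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}
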