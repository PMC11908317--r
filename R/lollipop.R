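#' Lollipop plot of protein-coordinate variants
#'
#' Plots each distinct protein-position variant in the cohort as a lollipop
#' whose height reflects the cohort allele count, colored by functional
#' effect, over colored boxes for the protein domains. Domains come from a
#' user-supplied table (name, start, end; 1-based inclusive residue
#' coordinates, overlaps permitted). Variants without a protein position --
#' non-coding and structural variants -- are not displayed; their count is
#' attached as the `nOmitted` attribute and a warning is emitted when
#' nothing is displayable.
#'
#' @param cohort a [Cohort-class].
#' @param proteinLength protein length in residues.
#' @param domains data.frame with columns `name`, `start`, `end`.
#' @param file optional output path; with a `.svg` extension the figure is
#'   written as SVG.
#' @return a `ggplot` object (invisibly when `file` is given) with
#'   attributes `nOmitted` and `positions` (the plotted table).
#' @export
renderLollipop <- function(cohort, proteinLength, domains =
                             data.frame(name = character(), start = integer(),
                                        end = integer()),
                           file = NULL) {
  stopifnot(proteinLength >= 1L)
  if (nrow(domains)) {
    bad <- domains$start < 1L | domains$start > domains$end |
      domains$end > proteinLength
    if (any(bad))
      stop("domain interval(s) outside 1..", proteinLength, ": ",
           paste(domains$name[bad], collapse = ", "))
  }
  rows <- list(); nOmitted <- 0L
  for (ind in cohort@individuals) {
    for (v in ind@variants) {
      if (is.na(v@proteinStart) || !is.na(v@structuralType)) {
        nOmitted <- nOmitted + v@alleleCount
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = v@proteinStart,
        effect = if (length(v@effects)) v@effects[1] else "other",
        n = v@alleleCount, stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(rows)) {
    df <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = df$n),
                            by = list(position = df$position, effect = df$effect),
                            FUN = sum)
    agg[order(agg$position), ]
  } else {
    warning("no variants with protein coordinates to display")
    data.frame(position = numeric(), effect = character(), count = integer())
  }

  domBand <- -max(c(positions$count, 1)) * 0.12
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(ggplot2::aes(xmin = 0.5, xmax = proteinLength + 0.5,
                                    ymin = domBand * 0.35, ymax = domBand * 0.65),
                       fill = "grey85") +
    ggplot2::labs(x = "protein residue", y = "allele count in cohort") +
    ggplot2::theme_minimal()
  if (nrow(domains)) {
    p <- p + ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = start - 0.5, xmax = end + 0.5,
                   ymin = domBand, ymax = 0, fill = name),
      alpha = 0.8) +
      ggplot2::scale_fill_brewer(palette = "Pastel1", name = "domain")
  }
  if (nrow(positions)) {
    p <- p +
      ggplot2::geom_segment(data = positions,
        ggplot2::aes(x = position, xend = position, y = 0, yend = count),
        linewidth = 0.6, color = "grey40") +
      ggplot2::geom_point(data = positions,
        ggplot2::aes(x = position, y = count, color = effect,
                     size = count)) +
      ggplot2::scale_size_continuous(range = c(2, 6), guide = "none")
  }
  p <- p + ggplot2::xlim(0, proteinLength + 1)
  attr(p, "nOmitted") <- nOmitted
  attr(p, "positions") <- positions
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 4, device = grDevices::svg)
    return(invisible(p))
  }
  p
}
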