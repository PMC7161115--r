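#' Functional-class composition of a locus set
#'
#' Percentage of loci per functional consequence class (one class per locus,
#' the most severe as resolved upstream; compound labels such as
#' `"stop_gained,start_lost"` pass through unchanged). Loci without an entry
#' in `classes` are counted as `"unannotated"`.
#'
#' @param subset A data frame of loci with columns `chrom` and `pos`
#'   (extra columns ignored); must be non-empty.
#' @param classes A data frame mapping loci to classes: `chrom`, `pos`,
#'   `class`.
#' @return A tibble `class`, `n`, `pct`; `pct` sums to 100.
#' @export
class_composition <- function(subset, classes) {
  if (nrow(subset) == 0) abort("empty locus subset")
  cls <- lookup_classes(subset, classes)
  out <- dplyr::count(tibble(class = cls), .data$class, name = "n")
  out$pct <- 100 * out$n / sum(out$n)
  dplyr::arrange(out, .data$class)
}

lookup_classes <- function(subset, classes) {
  key <- paste(subset$chrom, subset$pos)
  ckey <- paste(classes$chrom, classes$pos)
  cls <- classes$class[match(key, ckey)]
  cls[is.na(cls)] <- "unannotated"
  cls
}

#' Relative class abundance of a subset against a background
#'
#' Ratio of class percentages, `composition(subset) / composition(background)`,
#' per class. A class absent from the subset gets ratio 0; a class absent
#' from the background gets a missing ratio.
#'
#' @inheritParams class_composition
#' @param background A data frame of background loci (`chrom`, `pos`);
#'   must be non-empty.
#' @return A tibble `class`, `pct_subset`, `pct_background`, `ratio`.
#' @export
relative_abundance <- function(subset, background, classes) {
  if (nrow(background) == 0) abort("empty background")
  cs <- class_composition(subset, classes)
  cb <- class_composition(background, classes)
  out <- dplyr::full_join(
    dplyr::rename(cs, pct_subset = "pct"),
    dplyr::rename(cb, pct_background = "pct"),
    by = "class", suffix = c("_subset", "_background")
  )
  out$pct_subset[is.na(out$pct_subset)] <- 0
  out$ratio <- ifelse(is.na(out$pct_background), NA_real_,
                      out$pct_subset / out$pct_background)
  dplyr::arrange(
    dplyr::select(out, "class", "pct_subset", "pct_background", "ratio"),
    .data$class
  )
}

#' Class abundance profiles across differentiation bins
#'
#' For each bin of a binned locus track (see [bin_by_fst()]), computes the
#' relative class abundance against all binned loci as the common background,
#' giving the class-by-differentiation profile.
#'
#' @param binned A locus track with a `bin` column from [bin_by_fst()].
#' @inheritParams class_composition
#' @return A long tibble: `bin`, `class`, `pct_bin`, `pct_background`,
#'   `ratio`.
#' @export
abundance_by_bin <- function(binned, classes) {
  assigned <- binned[!is.na(binned$bin), ]
  if (nrow(assigned) == 0) abort("no loci assigned to a bin")
  purrr::map_dfr(levels(droplevels(assigned$bin)), function(b) {
    sub <- assigned[assigned$bin == b, ]
    ra <- relative_abundance(sub, assigned, classes)
    ra <- dplyr::rename(ra, pct_bin = "pct_subset")
    dplyr::bind_cols(tibble(bin = b), ra)
  })
}

#' Bar chart of class abundance across differentiation bins
#'
#' @param x Output of [abundance_by_bin()].
#' @param min_pct Hide classes rarer than this background percentage
#'   (default 0.1) to keep the panel readable.
#' @return A ggplot object.
#' @export
plot_abundance_bins <- function(x, min_pct = 0.1) {
  d <- x[x$pct_background >= min_pct, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$bin, .data$ratio, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "differentiation bin", y = "relative abundance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
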