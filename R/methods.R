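# S3 methods for the caller result objects.

#' @export
print.pod_regions <- function(x, ...) {
  cat("Collapsed candidate regions: ", nrow(x$regions), " region(s) from ",
      nrow(x$calls), " site call(s)",
      if (isTRUE(x$merge_single_discordant))
        " (single-discordant merge on)" else "", "\n", sep = "")
  if (nrow(x$regions)) print(utils::head(x$regions, 10L))
  invisible(x)
}

#' @export
print.pod_dmr <- function(x, ...) {
  cat("Parent-of-origin DMR call set (", x$mode, " mode)\n", sep = "")
  cat("  ", nrow(x$regions), " region(s) after filtering\n", sep = "")
  if (nrow(x$regions)) {
    print(x$regions[, c("chrom", "start", "end", "direction", "n_sites")])
  }
  invisible(x)
}

#' Summarize a DMR call set
#'
#' Prints the parameter set and the filter attrition funnel (sites in,
#' sites qualifying, regions before/after each filter), then the region
#' table.
#'
#' @param object A `pod_dmr`.
#' @param ... Unused.
#' @return Invisibly, a list with `regions`, `params`, `attrition`.
#' @export
summary.pod_dmr <- function(object, ...) {
  cat("Parent-of-origin DMR call set (", object$mode, " mode)\n\n",
      sep = "")
  cat("Parameters:\n")
  for (p in names(object$params)) {
    cat(sprintf("  %-24s %s\n", p,
                paste(object$params[[p]], collapse = ", ")))
  }
  cat("\nFilter funnel:\n")
  for (a in names(object$attrition)) {
    cat(sprintf("  %-36s %d\n", a, object$attrition[[a]]))
  }
  cat("\nRegions:\n")
  if (nrow(object$regions)) print(object$regions) else cat("  none\n")
  invisible(list(regions = object$regions, params = object$params,
                 attrition = object$attrition))
}

#' @export
as.data.frame.pod_dmr <- function(x, ...) x$regions

#' @export
as.data.frame.pod_regions <- function(x, ...) x$regions

#' Plot per-site percent methylation around called regions
#'
#' Base-graphics track of per-category (trio mode) or per-sample
#' (hemizygous mode) percent methylation along position, with called
#' regions shaded.
#'
#' @param x A `pod_dmr`.
#' @param region Row index of the region to centre on (default 1); ignored
#'   when `xlim` is given.
#' @param flank Sites of context shown either side of the region.
#' @param xlim Optional explicit position window.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pod_dmr <- function(x, region = 1L, flank = 10L, xlim = NULL, ...) {
  calls <- x$calls
  if (is.null(xlim)) {
    if (nrow(x$regions) == 0) {
      stop("no regions to plot; supply xlim", call. = FALSE)
    }
    reg <- x$regions[region, ]
    idx <- which(calls$chrom == reg$chrom & calls$pos >= reg$start &
                   calls$pos <= reg$end)
    lo <- max(1L, min(idx) - flank)
    hi <- min(nrow(calls), max(idx) + flank)
    window <- calls[lo:hi, ]
    xlim <- range(window$pos)
  } else {
    window <- calls[calls$pos >= xlim[1L] & calls$pos <= xlim[2L], ]
  }
  if (x$mode == "blood") {
    series <- list(`upd(16)mat` = window$pct_mat,
                   biparental = window$pct_bip,
                   `upd(16)pat` = window$pct_pat)
  } else {
    series <- list(hemizygous = window$pct_hemi)
  }
  cols <- c("#c0392b", "#7f8c8d", "#2980b9")[seq_along(series)]
  plot(NA, xlim = xlim, ylim = c(0, 100), xlab = "position",
       ylab = "% methylation", ...)
  inwin <- x$regions$end >= xlim[1L] & x$regions$start <= xlim[2L]
  if (any(inwin)) {
    rect(x$regions$start[inwin], -5, x$regions$end[inwin], 105,
         col = adjustcolor("gold", 0.25), border = NA)
  }
  for (i in seq_along(series)) {
    points(window$pos, series[[i]], col = cols[i], pch = 19, cex = 0.6)
  }
  legend("topright", legend = names(series), col = cols, pch = 19,
         bg = "white", cex = 0.8)
  invisible(x)
}
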