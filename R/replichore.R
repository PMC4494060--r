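## Replichore architecture: GC-skew profiling, ori/ter localization, dif-site
## scanning, circular distance-to-ori, growth-rate and replication-ratio (R)
## calculations.

#' GC-skew profile of a circular genome
#'
#' Slides a window around the circular chromosome and computes the GC skew
#' (G - C) / (G + C) per window, together with the cumulative skew series
#' whose extrema mark the replication origin and terminus.
#'
#' @param genome a [circular_genome()] with sequence.
#' @param window window size in bp (must not exceed the genome length).
#' @param step step between window starts in bp.
#' @return an object of class `skew_profile`: window centers (bp, 0-based),
#'   per-window skew in \[-1, 1\], cumulative skew, and a logical `zero_gc`
#'   marking windows without any G or C (their skew is set to 0).
#' @export
gc_skew_profile <- function(genome, window = 10000L, step = 1000L) {
  if (is.null(genome$sequence)) stop_arch("genome has no sequence")
  window <- as.integer(window); step <- as.integer(step)
  if (window <= 0L || step <= 0L) stop_arch("window and step must be > 0")
  L <- genome$length
  if (window > L) stop_arch("window exceeds genome length")
  chars <- strsplit(genome$sequence, "")[[1]]
  ## extend by window-1 so every circular window is a contiguous slice
  ext <- c(chars, chars[seq_len(window - 1L)])
  gcum <- cumsum(ext == "G")
  ccum <- cumsum(ext == "C")
  starts <- seq.int(0L, L - 1L, by = step)       # 0-based window starts
  lo <- starts                                    # index before window start
  hi <- starts + window                           # index of window end
  g <- gcum[hi] - c(0, gcum)[lo + 1L]
  cc <- ccum[hi] - c(0, ccum)[lo + 1L]
  tot <- g + cc
  zero <- tot == 0L
  skew <- ifelse(zero, 0, (g - cc) / ifelse(zero, 1L, tot))
  structure(list(genome_id = genome$id, window = window, step = step,
                 length = L,
                 centers = as.integer(pmod(starts + window %/% 2L, L)),
                 skew = skew, cumulative = cumsum(skew), gc_count = tot,
                 zero_gc = zero),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat("GC-skew profile of '", x$genome_id, "': ", length(x$centers),
      " windows (window = ", x$window, " bp, step = ", x$step, " bp)\n",
      sep = "")
  cat("  cumulative skew range: ",
      format(range(x$cumulative), digits = 4)[1], " .. ",
      format(range(x$cumulative), digits = 4)[2], "\n", sep = "")
  invisible(x)
}

#' @export
plot.skew_profile <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$centers, x$skew, type = "l", xlab = "position (bp)",
                 ylab = "GC skew", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$centers, x$cumulative, type = "l",
                 xlab = "position (bp)", ylab = "cumulative skew", ...)
  invisible(x)
}

#' Locate ori and ter from a GC-skew profile
#'
#' The cumulative GC skew of a chromosome with two replichores descends along
#' one arc and ascends along the other; its global extrema sit at the
#' replication origin and terminus. Under the default polarity convention the
#' leading strand is G-rich, so the cumulative minimum marks ori and the
#' maximum marks ter; `polarity = "c_leading"` flips the assignment.
#'
#' @param profile a [gc_skew_profile()] result with at least 10 windows.
#' @param polarity `"g_leading"` (default; min = ori) or `"c_leading"`.
#' @param tol_factor flat-signal guard. Without replichore structure the
#'   cumulative skew is a random walk whose range grows like
#'   `sigma * sqrt(n * window / step)`, where `sigma` is the binomial
#'   sampling noise of a window's skew (about `1 / sqrt(G + C)`). The
#'   detector refuses to call ori/ter when the observed cumulative range is
#'   below `tol_factor` times that null walk scale; at the default 4 a
#'   signal-free genome exceeds the guard with probability on the order of
#'   1e-4, while a genuine two-replichore signal grows linearly with the
#'   number of windows and clears it comfortably.
#' @return list with `ori`, `ter` (bp positions of the extremal window
#'   centers), `uncertainty_bp` (the window size) and `signal_to_null` (the
#'   guard statistic).
#' @export
detect_ori_ter <- function(profile, polarity = c("g_leading", "c_leading"),
                           tol_factor = 4) {
  polarity <- match.arg(polarity)
  n <- length(profile$centers)
  if (n < 10L)
    stop_arch("need at least 10 windows to call ori/ter")
  cum <- profile$cumulative
  sigma <- mean(1 / sqrt(pmax(profile$gc_count, 1L)))
  null_scale <- sigma * sqrt(n * profile$window / profile$step)
  t_stat <- diff(range(cum)) / null_scale
  if (t_stat < tol_factor)
    stop_arch("no replichore signal: cumulative skew range within the ",
              "random-walk null (statistic ", format(t_stat, digits = 3),
              " < ", tol_factor, ")")
  imin <- which.min(cum); imax <- which.max(cum)
  if (polarity == "g_leading") {
    ori <- profile$centers[imin]; ter <- profile$centers[imax]
  } else {
    ori <- profile$centers[imax]; ter <- profile$centers[imin]
  }
  list(ori = ori, ter = ter, uncertainty_bp = profile$window,
       signal_to_null = t_stat)
}

#' Scan a circular genome for dif-like motifs
#'
#' IUPAC-aware circular search on both strands with up to `max_mismatch`
#' mismatches. The dif motif (where chromosome dimers are resolved) is an
#' independent marker of the replication terminus; the consensus must be
#' supplied by the user.
#'
#' @param genome a [circular_genome()] with sequence.
#' @param motif IUPAC motif string.
#' @param max_mismatch maximum number of mismatches allowed.
#' @return data.frame with 0-based `position` (forward-strand coordinate of
#'   the match start), `strand` and `mismatches`, ordered by position.
#' @export
find_dif_sites <- function(genome, motif, max_mismatch = 0L) {
  if (is.null(genome$sequence)) stop_arch("genome has no sequence")
  motif <- toupper(motif)
  if (!nzchar(motif)) stop_arch("empty motif")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(motif, "")[[1]], iupac)
  if (length(bad))
    stop_arch("invalid IUPAC character(s) in motif: ",
              paste(unique(bad), collapse = ", "))
  L <- genome$length
  k <- nchar(motif)
  if (k > L) stop_arch("motif longer than genome")
  ext <- paste0(genome$sequence,
                substr(genome$sequence, 1L, k - 1L))
  subject <- Biostrings::DNAString(ext)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = max_mismatch,
                                     fixed = FALSE)
    st <- Biostrings::start(hits)
    st <- st[st <= L]
    if (!length(st))
      return(data.frame(position = integer(0), strand = character(0),
                        mismatches = integer(0)))
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subject,
                                      starting.at = st, fixed = FALSE)
    data.frame(position = st - 1L, strand = strand, mismatches = mm,
               stringsAsFactors = FALSE)
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  out <- rbind(scan_one(motif, "+"), scan_one(rc, "-"))
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Gene midpoint on a circular chromosome
#'
#' Integer midpoint along the gene's span (handles wrap-around genes),
#' modulo the genome length.
#'
#' @param genes a [gene_table()].
#' @param L genome length in bp.
#' @return integer vector of midpoints (0-based).
#' @export
gene_midpoint <- function(genes, L) {
  span <- ifelse(genes$wraps, genes$end + L - genes$start,
                 genes$end - genes$start)
  as.integer(pmod(genes$start + span %/% 2L, L))
}

#' Circular distance from gene midpoints to the replication origin
#'
#' @param genes a [gene_table()] (rows must belong to `genome`).
#' @param genome a [circular_genome()] with ori set.
#' @return integer vector of distances in \[0, L/2\].
#' @export
distance_to_ori <- function(genes, genome) {
  if (is.null(genome$ori)) stop_arch("genome ori is not set")
  mid <- gene_midpoint(genes, genome$length)
  as.integer(circ_dist(mid, genome$ori, genome$length))
}

#' Estimate the minimal doubling time from a growth curve
#'
#' Ordinary least squares of log(OD) on time within the exponential phase;
#' the doubling time is log(2) divided by the fitted slope. If no window is
#' given, the exponential phase is selected automatically as the contiguous
#' run of at least 4 points with positive slope maximizing the R-squared of
#' the log-linear fit (longest such run on ties).
#'
#' @param times sampling times in minutes.
#' @param od optical density readings (> 0 within the fitted window).
#' @param window optional `c(t0, t1)` restricting the fit.
#' @return object of class `growth_fit` with `slope` (per minute, natural
#'   log), `intercept`, `doubling_time` (min), `window` and `r_squared`.
#' @export
estimate_doubling_time <- function(times, od, window = NULL) {
  stopifnot(length(times) == length(od))
  ord <- order(times)
  times <- times[ord]; od <- od[ord]
  fit_run <- function(idx) {
    t <- times[idx]; y <- log(od[idx])
    vx <- stats::var(t)
    if (vx == 0) return(NULL)
    slope <- stats::cov(t, y) / vx
    r2 <- if (stats::var(y) == 0) 1 else stats::cor(t, y)^2
    list(slope = slope, intercept = mean(y) - slope * mean(t), r2 = r2,
         idx = idx)
  }
  if (!is.null(window)) {
    idx <- which(times >= window[1] & times <= window[2])
    if (length(idx) < 3L) stop_arch("fewer than 3 points in window")
    if (any(od[idx] <= 0)) stop_arch("non-positive OD in window")
    best <- fit_run(idx)
    if (is.null(best) || best$slope <= 0) stop_arch("no growth detected")
  } else {
    ## exponential-phase auto-selection: among contiguous runs of >= 4 points
    ## with positive slope, take the longest run whose R^2 is within 0.01 of
    ## the best (a short run can win R^2 by luck; near-ties go to length)
    n <- length(times)
    fits <- list()
    for (i in seq_len(n)) {
      for (j in seq.int(i + 3L, n)) {
        if (j > n) break
        idx <- i:j
        if (any(od[idx] <= 0)) next
        f <- fit_run(idx)
        if (is.null(f) || f$slope <= 0) next
        fits[[length(fits) + 1L]] <- f
      }
    }
    if (!length(fits)) stop_arch("no growth detected")
    r2s <- vapply(fits, `[[`, numeric(1), "r2")
    lens <- vapply(fits, function(f) length(f$idx), numeric(1))
    near <- r2s >= max(r2s) - 0.01
    pick <- which(near)[order(-lens[near], -r2s[near])][1]
    best <- fits[[pick]]
  }
  structure(list(slope = best$slope, intercept = best$intercept,
                 doubling_time = log(2) / best$slope,
                 window = c(times[best$idx[1]],
                            times[best$idx[length(best$idx)]]),
                 r_squared = best$r2, n_points = length(best$idx)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential growth fit: doubling time %.2f min (slope %.5f /min, R^2 %.4f, %d points in [%g, %g] min)\n",
    x$doubling_time, x$slope, x$r_squared, x$n_points, x$window[1],
    x$window[2]))
  invisible(x)
}

#' Replichore replication ratio R
#'
#' R is the time a fork needs to replicate one replichore (half the genome at
#' the given fork speed) divided by the minimal doubling time. R > 0.5
#' implies overlapping replication rounds and hence gene-dosage gradients
#' along the ori-ter axis.
#'
#' @param genome_length genome length in bp.
#' @param speed replication fork speed in nucleotides per second.
#' @param doubling_time minimal doubling time in minutes.
#' @return object of class `replication_params` with the full-precision `R`,
#'   its 2-decimal rounding `R_2dp`, and the inputs.
#' @export
replication_ratio_R <- function(genome_length, speed, doubling_time) {
  if (genome_length <= 0 || speed <= 0 || doubling_time <= 0)
    stop_arch("all inputs must be positive")
  replication_s <- (genome_length / 2) / speed
  R <- replication_s / (doubling_time * 60)
  structure(list(genome_length = genome_length, replication_speed = speed,
                 doubling_time = doubling_time, R = R,
                 R_2dp = round_half_up(R, 2L)),
            class = "replication_params")
}

#' @export
print.replication_params <- function(x, ...) {
  cat(sprintf(
    "Replication ratio R = %.2f (genome %s bp, fork speed %g nt/s, doubling time %g min)\n",
    x$R_2dp, format(x$genome_length, big.mark = ","), x$replication_speed,
    x$doubling_time))
  invisible(x)
}
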