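# Droplet digital PCR quantification: invert the Poisson zero class to get
# copies per droplet, and form mtDNA/nDNA ratios with log-normal
# delta-method intervals. Ratios are unitless, so the volume-to-
# concentration conversion cancels and is omitted.

#' Droplet tallies for one assay
#'
#' @param assay Target name (e.g. `"mt-Co1"`, `"mt-Nd5"`, `"Vdac1"`).
#' @param n_total Total droplets (> 0).
#' @param n_negative Negative droplets, in `[0, n_total]`.
#' @return A list of class `droplet_counts`.
#' @export
droplet_counts <- function(assay, n_total, n_negative) {
  n_total <- as.integer(n_total); n_negative <- as.integer(n_negative)
  if (n_total <= 0L) stop("n_total must be > 0")
  if (n_negative < 0L || n_negative > n_total)
    stop("n_negative must lie in [0, n_total]")
  structure(list(assay = assay, n_total = n_total, n_negative = n_negative),
            class = "droplet_counts")
}

#' Copies per droplet from the Poisson zero class
#'
#' With droplets occupied according to a Poisson distribution, the fraction
#' of negative droplets is `exp(-lambda)`, so
#' `lambda = -log(n_negative / n_total)` copies per droplet. The standard
#' error follows from the delta method:
#' `sqrt((n_total - n_negative) / (n_total * n_negative))`.
#'
#' A fully negative assay gives `lambda = 0` (valid); a fully positive assay
#' is saturated and carries no information about `lambda`, which is an
#' error.
#'
#' @param counts A [droplet_counts()] object.
#' @return A list with `assay`, `lambda` and `se`.
#' @examples
#' droplet_concentration(droplet_counts("mt-Co1", 10000, 5000))$lambda # ~log(2)
#' @export
droplet_concentration <- function(counts) {
  stopifnot(inherits(counts, "droplet_counts"))
  if (counts$n_negative == 0L)
    stop("saturated assay: no negative droplets, lambda is unbounded")
  nt <- as.numeric(counts$n_total); nn <- as.numeric(counts$n_negative)
  lambda <- -log(nn / nt)
  se <- sqrt((nt - nn) / (nt * nn))
  list(assay = counts$assay, lambda = lambda, se = se)
}

#' Copy-number ratio of two ddPCR assays
#'
#' Ratio of copies per droplet, numerator over denominator (e.g.
#' mt-Co1/Vdac1 for the mtDNA/nDNA ratio). The 95% interval comes from a
#' normal approximation on the log scale with summed squared relative
#' standard errors of the two concentrations.
#'
#' @param num,den [droplet_counts()] for numerator and denominator assays.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `copy_ratio` with `numerator_assay`,
#'   `denominator_assay`, `lambda_num`, `lambda_den`, `ratio`, `ci_low`,
#'   `ci_high`.
#' @export
copy_ratio <- function(num, den, conf_level = 0.95) {
  cn <- droplet_concentration(num)
  cd <- droplet_concentration(den)
  if (cd$lambda == 0)
    stop("denominator zero: assay '", cd$assay, "' has no positive droplets")
  ratio <- cn$lambda / cd$lambda
  if (cn$lambda == 0) {
    ci <- c(NA_real_, NA_real_)
  } else {
    rel2 <- (cn$se / cn$lambda)^2 + (cd$se / cd$lambda)^2
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- ratio * exp(c(-1, 1) * z * sqrt(rel2))
  }
  structure(list(numerator_assay = cn$assay, denominator_assay = cd$assay,
                 lambda_num = cn$lambda, lambda_den = cd$lambda,
                 ratio = ratio, ci_low = ci[1L], ci_high = ci[2L]),
            class = "copy_ratio")
}

#' @export
print.copy_ratio <- function(x, ...) {
  cat(sprintf("<copy_ratio> %s/%s = %.4f [%.4f, %.4f]\n",
              x$numerator_assay, x$denominator_assay, x$ratio,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Copy-number ratios for a droplet-count table
#'
#' Takes a long table (`sample`, `assay`, `n_total`, `n_negative`) and
#' computes, per sample, the ratio of each numerator assay against the
#' common denominator assay.
#'
#' @param droplets Data frame or path to a TSV with columns `sample`,
#'   `assay`, `n_total`, `n_negative`.
#' @param numerators Assays to put in the numerator
#'   (default `c("mt-Co1", "mt-Nd5")`).
#' @param denominator The single-copy nuclear reference assay
#'   (default `"Vdac1"`).
#' @return Data frame: `sample`, `numerator`, `denominator`, `ratio`,
#'   `ci_low`, `ci_high`.
#' @export
copy_ratio_table <- function(droplets, numerators = c("mt-Co1", "mt-Nd5"),
                             denominator = "Vdac1") {
  if (is.character(droplets) && length(droplets) == 1L)
    droplets <- utils::read.delim(droplets, check.names = FALSE)
  need <- c("sample", "assay", "n_total", "n_negative")
  miss <- setdiff(need, names(droplets))
  if (length(miss))
    stop("droplet table is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(droplets$sample)) {
    d <- droplets[droplets$sample == s, ]
    den_row <- d[d$assay == denominator, ]
    if (nrow(den_row) == 0L) next
    den <- droplet_counts(denominator, den_row$n_total[1L], den_row$n_negative[1L])
    for (a in intersect(numerators, d$assay)) {
      num_row <- d[d$assay == a, ][1L, ]
      cr <- copy_ratio(droplet_counts(a, num_row$n_total, num_row$n_negative), den)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, numerator = a, denominator = denominator,
        ratio = cr$ratio, ci_low = cr$ci_low, ci_high = cr$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
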