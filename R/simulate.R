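# Synthetic-data generators with ground truth: aligned reads over an
# anchored homopolymer with a slippage error model, droplet counts, and
# lifespan cohorts with a heteroplasmy effect. All generators are seeded
# and byte-deterministic given identical parameters.

#' Build a reference sequence around a motif site
#'
#' Embeds the anchor base, the reference homopolymer run and a terminator
#' base at the site's true coordinates, flanked by `flank` bases of a
#' non-confounding pattern on each side. The returned sequence starts at
#' reference coordinate `anchor_position - flank`, so read positions keep
#' the real mtDNA numbering.
#'
#' @param site A [motif_site()].
#' @param flank Flank width in bases on each side (>= 1; must be at least
#'   the read length for read simulation).
#' @return A list with `seq` (character string), `start` (coordinate of its
#'   first base), `run_start`, `terminator_position` and `site`.
#' @export
make_reference <- function(site, flank = 200L) {
  flank <- as.integer(flank)
  if (flank < 1L) stop("flank must be >= 1")
  avoid <- c(site$anchor_base, site$repeat_base)
  pool <- setdiff(c("A", "C", "G", "T"), avoid)
  # deterministic flank pattern free of anchor/repeat bases so the motif
  # grammar scan cannot latch onto flank sequence
  pat <- function(n) paste(rep_len(pool, n), collapse = "")
  run_start <- site$anchor_position + 1L
  term_pos <- run_start + site$reference_run_length
  seq <- paste0(pat(flank), site$anchor_base,
                strrep(site$repeat_base, site$reference_run_length),
                pool[1L], pat(flank))
  list(seq = seq, start = site$anchor_position - flank,
       run_start = run_start, terminator_position = term_pos, site = site)
}

# Geometric-tailed slippage magnitudes: P(m) = (1-q) q^(m-1), m >= 1.
.slip_magnitude <- function(n, q) stats::rgeom(n, prob = 1 - q) + 1L

#' Simulate aligned reads over a homopolymer site
#'
#' Each read draws a true repeat-length allele from `allele_fractions`;
#' with probability `slippage_rate` the observed run length slips by a
#' geometric-tailed magnitude (symmetric sign), emulating polymerase
#' stutter; per-base substitutions are applied at `substitution_rate`; base
#' qualities are drawn from a normal Phred model. The CIGAR encodes the
#' run-length difference as an indel placed at the run start (left-aligned,
#' like an aligner) or run end (`indel_align = "right"`, for
#' placement-invariance testing). Every read is placed so that it spans the
#' anchor and, barring errors, the run terminator. Optional soft clips and
#' PCR duplicate copies exercise the downstream filters.
#'
#' @param site A [motif_site()].
#' @param allele_fractions Named numeric vector: run length -> fraction
#'   (must sum to 1).
#' @param n_reads Number of fragments to simulate.
#' @param read_length Maximum read length in bases (before trimming).
#' @param length_jitter Reads are uniformly `read_length - 0:length_jitter`
#'   bases long, emulating adapter/quality trimming of paired-end
#'   libraries. Coordinate-plus-structure duplicate marking relies on this
#'   natural variability; identical-length reads at saturating depth would
#'   collide.
#' @param substitution_rate Per-base substitution probability.
#' @param slippage_rate Per-read probability of a slippage event.
#' @param slip_geom Geometric tail parameter q for slip magnitudes
#'   (P(m) proportional to q^(m-1)).
#' @param quality_mean,quality_sd Phred quality model.
#' @param paired Emit paired-complete SAM flags (the non-spanning mate is
#'   not emitted; it carries no motif information).
#' @param flank Reference flank width (must be >= `read_length`).
#' @param indel_align `"left"` or `"right"` placement of run indels.
#' @param soft_clip_rate Probability a read carries a soft clip.
#' @param soft_clip_max Maximum soft-clip length.
#' @param duplicate_rate Expected fraction of fragments that receive one
#'   extra PCR duplicate copy.
#' @param seed Optional integer seed.
#' @return A list with `reads` (an `aligned_reads` table), `truth` (one row
#'   per emitted read: `read_name`, `true_allele`, `observed_run`,
#'   `slipped`, `n_substitutions`, `start`, `duplicate_of`), `reference`
#'   (from [make_reference()]) and `site`.
#' @export
simulate_polyA_reads <- function(site,
                                 allele_fractions = c("11" = 1),
                                 n_reads = 1000L,
                                 read_length = 150L,
                                 length_jitter = 30L,
                                 substitution_rate = 0.002,
                                 slippage_rate = 0.005,
                                 slip_geom = 0.2,
                                 quality_mean = 35,
                                 quality_sd = 3,
                                 paired = TRUE,
                                 flank = 200L,
                                 indel_align = c("left", "right"),
                                 soft_clip_rate = 0,
                                 soft_clip_max = 10L,
                                 duplicate_rate = 0,
                                 seed = NULL) {
  indel_align <- match.arg(indel_align)
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(allele_fractions) - 1) > 1e-8)
    stop("allele_fractions must sum to 1")
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            slippage_rate >= 0, slippage_rate < 1)
  if (flank < read_length)
    stop("flank must be at least the read length")
  ref <- make_reference(site, flank)
  lengths <- as.integer(names(allele_fractions))
  R <- site$reference_run_length
  rs <- ref$run_start
  anchor <- site$anchor_position
  length_jitter <- as.integer(length_jitter)
  min_len <- read_length - length_jitter
  # the shortest read must cover one base before the anchor and the terminator
  max_obs_guess <- max(lengths) + 8L
  if (min_len < (rs - (anchor - 1L)) + max_obs_guess + 1L)
    stop("read_length too short to span anchor, run and terminator")

  n <- as.integer(n_reads)
  true_allele <- lengths[sample.int(length(lengths), n, replace = TRUE,
                                    prob = allele_fractions)]
  slipped <- stats::runif(n) < slippage_rate
  nslip <- sum(slipped)
  slip <- integer(n)
  if (nslip > 0L)
    slip[slipped] <- .slip_magnitude(nslip, slip_geom) *
      sample(c(-1L, 1L), nslip, replace = TRUE)
  # clamp: a run cannot be negative, and the geometric tail must not push
  # the observed run past what a read can span
  obs <- pmin(pmax(true_allele + slip, 0L), min_len - 10L)
  rlen <- read_length - (if (length_jitter > 0L)
    sample.int(length_jitter + 1L, n, replace = TRUE) - 1L else 0L)

  # start positions: uniform over starts that keep the motif window visible
  lo_start <- rs - (rlen - obs - 1L)             # terminator still in read
  hi_start <- anchor - 1L                        # must cover base before anchor
  start <- as.integer(lo_start + floor(stats::runif(n) * (hi_start - lo_start + 1L)))

  idx <- function(p) p - ref$start + 1L
  qmat <- matrix(pmin(pmax(round(stats::rnorm(n * read_length, quality_mean,
                                              quality_sd)), 2L), 41L),
                 nrow = n)
  bases <- c("A", "C", "G", "T")

  qname <- sprintf("sim%06d", seq_len(n))
  seqs <- character(n); quals <- character(n); cigars <- character(n)
  nsub <- integer(n)
  for (i in seq_len(n)) {
    s <- start[i]; o <- obs[i]; L <- rlen[i]
    pre <- rs - s                      # bases before the run (incl. anchor)
    tail_n <- L - pre - o
    left <- substr(ref$seq, idx(s), idx(rs - 1L))
    right <- if (tail_n > 0L)
      substr(ref$seq, idx(rs + R), idx(rs + R) + tail_n - 1L) else ""
    sq <- paste0(left, strrep(site$repeat_base, o), right)
    if (o == R) {
      cg <- paste0(L, "M")
    } else if (o > R) {
      ins <- o - R
      cg <- if (indel_align == "left")
        paste0(pre, "M", ins, "I", L - pre - ins, "M")
      else
        paste0(pre + R, "M", ins, "I", L - pre - R - ins, "M")
    } else {
      del <- R - o
      cg <- if (indel_align == "right" && o > 0L)
        paste0(pre + o, "M", del, "D", L - pre - o, "M")
      else
        paste0(pre, "M", del, "D", L - pre, "M")
    }
    # substitutions
    k <- stats::rbinom(1L, L, substitution_rate)
    if (k > 0L) {
      at <- sample.int(L, k)
      ch <- strsplit(sq, "", fixed = TRUE)[[1L]]
      for (j in at) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
      sq <- paste(ch, collapse = "")
      nsub[i] <- k
    }
    # optional soft clips (prepended; consume query only)
    if (soft_clip_rate > 0 && stats::runif(1L) < soft_clip_rate) {
      cl <- sample.int(soft_clip_max, 1L)
      sq <- paste0(paste(sample(bases, cl, replace = TRUE), collapse = ""), sq)
      cg <- paste0(cl, "S", cg)
      qmat_extra <- pmin(pmax(round(stats::rnorm(cl, quality_mean, quality_sd)),
                              2L), 41L)
      quals[i] <- intToUtf8(c(qmat_extra, qmat[i, seq_len(L)]) + 33L)
    } else {
      quals[i] <- intToUtf8(qmat[i, seq_len(L)] + 33L)
    }
    seqs[i] <- sq
    cigars[i] <- cg
  }
  flag <- if (paired) 99L else 0L
  # Nextera-like fragment lengths give each read a distinct fragment
  # identity (read start + mate start), which duplicate marking keys on
  frag <- sample(250:450, n, replace = TRUE)
  pnext <- if (paired) start + frag - rlen else 0L
  reads <- data.frame(qname = qname, flag = flag, rname = "chrM",
                      pos = start, mapq = 60L, cigar = cigars,
                      rnext = if (paired) "=" else "*",
                      pnext = as.integer(pnext),
                      tlen = if (paired) as.integer(frag) else 0L,
                      seq = seqs, qual = quals, stringsAsFactors = FALSE)
  truth <- data.frame(read_name = qname, true_allele = true_allele,
                      observed_run = obs, slipped = slipped,
                      n_substitutions = nsub, start = start,
                      duplicate_of = NA_character_,
                      stringsAsFactors = FALSE)
  if (duplicate_rate > 0) {
    dup_of <- which(stats::runif(n) < duplicate_rate)
    if (length(dup_of)) {
      copies <- reads[dup_of, , drop = FALSE]
      copies$qname <- paste0(copies$qname, "_dup")
      # PCR copies share sequence and coordinates; qualities re-drawn
      copies$qual <- vapply(nchar(copies$seq), function(L)
        intToUtf8(pmin(pmax(round(stats::rnorm(L, quality_mean, quality_sd)),
                            2L), 41L) + 33L), character(1L))
      reads <- rbind(reads, copies)
      tr_copy <- truth[dup_of, , drop = FALSE]
      tr_copy$duplicate_of <- tr_copy$read_name
      tr_copy$read_name <- copies$qname
      truth <- rbind(truth, tr_copy)
    }
  }
  rownames(reads) <- NULL
  rownames(truth) <- NULL
  reads$is_paired_complete <- bitwAnd(reads$flag, .FLAG_PAIRED) > 0L &
    bitwAnd(reads$flag, .FLAG_MATE_UNMAP) == 0L
  reads$is_duplicate <- FALSE
  class(reads) <- c("aligned_reads", "data.frame")
  list(reads = reads, truth = truth, reference = ref, site = site)
}

#' Simulate a ddPCR droplet assay
#'
#' Each droplet is negative with probability `exp(-lambda)` (the Poisson
#' zero class).
#'
#' @param lambda_true True copies per droplet (>= 0).
#' @param n_total Number of droplets.
#' @param assay Assay label.
#' @param seed Optional integer seed.
#' @return A [droplet_counts()] object.
#' @export
simulate_droplets <- function(lambda_true, n_total, assay = "assay",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lambda_true >= 0, n_total > 0)
  n_neg <- stats::rbinom(1L, as.integer(n_total), exp(-lambda_true))
  droplet_counts(assay, n_total, n_neg)
}

# Azzalini-representation skew-normal draws (direct parameterisation).
.rskewnorm <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- abs(stats::rnorm(n)); u1 <- stats::rnorm(n)
  location + scale * (delta * u0 + sqrt(1 - delta^2) * u1)
}

# Truncated-normal draws on [0, 1]; element-wise rejection keeps each
# draw tied to its own mean.
.rtruncnorm01 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0 | x > 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < 0 | x[bad] > 1]
  }
  x
}

#' Simulate a lifespan cohort with a heteroplasmy effect
#'
#' Per animal, heteroplasmy is a truncated normal on `[0, 1]` around its
#' strain mean; lifespan is a skew-normal draw (left-skewed, as moribund-age
#' distributions are) shifted by `lifespan_slope` days per unit
#' heteroplasmy above the across-strain mean; censoring is Bernoulli. A
#' ddPCR-style copy ratio declining with heteroplasmy is attached with
#' log-normal noise. Defaults mirror a two-strain female ageing cohort:
#' strain heteroplasmy means 0.10 and 0.22, and a slope of -400 days/unit so
#' the strain gap translates into roughly a 50-day lifespan difference.
#'
#' @param n_per_strain Animals per strain.
#' @param het_mean Named numeric: strain -> mean heteroplasmy fraction.
#' @param het_sd Heteroplasmy SD (fraction).
#' @param lifespan_location,lifespan_scale,lifespan_skew Skew-normal
#'   parameters of the baseline lifespan distribution (days).
#' @param lifespan_slope Days of lifespan change per unit heteroplasmy
#'   (negative: higher heteroplasmy shortens life).
#' @param censor_rate Probability an animal is censored.
#' @param sex Sex label for all animals.
#' @param copy_ratio_base Copy ratio at zero heteroplasmy.
#' @param copy_ratio_slope Copy-ratio change per unit heteroplasmy.
#' @param copy_ratio_cv Log-normal coefficient of variation of the ratio.
#' @param seed Optional integer seed.
#' @return A data frame (`animal_id`, `strain`, `sex`, `lifespan_days`,
#'   `event`, `het_12A`, `copy_ratio`) with the generating parameters in
#'   `attr(, "params")`.
#' @export
simulate_cohort <- function(n_per_strain = 85L,
                            het_mean = c(B6 = 0.10, AKR = 0.22),
                            het_sd = 0.06,
                            lifespan_location = 820,
                            lifespan_scale = 160,
                            lifespan_skew = -4,
                            lifespan_slope = -400,
                            censor_rate = 0.08,
                            sex = "F",
                            copy_ratio_base = 150,
                            copy_ratio_slope = -120,
                            copy_ratio_cv = 0.15,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(censor_rate >= 0, censor_rate < 1, lifespan_scale > 0,
            het_sd > 0)
  strains <- names(het_mean)
  n <- n_per_strain * length(strains)
  strain <- rep(strains, each = n_per_strain)
  het <- .rtruncnorm01(n, het_mean[strain], het_sd)
  base_life <- .rskewnorm(n, lifespan_location, lifespan_scale, lifespan_skew)
  lifespan <- pmax(base_life + lifespan_slope * (het - mean(het_mean)), 30)
  event <- stats::runif(n) >= censor_rate
  sdlog <- sqrt(log(1 + copy_ratio_cv^2))
  cr <- pmax(copy_ratio_base + copy_ratio_slope * het, 1) *
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  out <- data.frame(
    animal_id = sprintf("%s_%03d", strain, stats::ave(seq_len(n), strain,
                                                      FUN = seq_along)),
    strain = strain, sex = sex, lifespan_days = lifespan,
    event = event, het_12A = het, copy_ratio = cr,
    stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_per_strain = n_per_strain,
                              het_mean = het_mean, het_sd = het_sd,
                              lifespan_location = lifespan_location,
                              lifespan_scale = lifespan_scale,
                              lifespan_skew = lifespan_skew,
                              lifespan_slope = lifespan_slope,
                              censor_rate = censor_rate)
  out
}
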