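# Pipeline orchestration: simulate -> call -> quantify -> correlate, each
# step a plain function over files or data frames so runs are seeded,
# diff-able and reproducible. All tabular outputs are header-rowed TSV.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort phenotype table
#'
#' @param path TSV with columns `animal_id`, `strain`, `sex`,
#'   `lifespan_days`, `event`, `het_12A` and optionally `copy_ratio`.
#' @return A data frame.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("animal_id", "strain", "sex", "lifespan_days", "event", "het_12A")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  df$event <- as.logical(df$event)
  df
}

#' Generate every pipeline input with ground truth
#'
#' Writes, under `out_dir`: `reads.sam` (aligned reads over the site),
#' `read_truth.tsv`, `cohort.tsv`, `droplets.tsv` and `reference.fa`. All
#' randomness flows from `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param site A [motif_site()] (default [oril_site()]).
#' @param read_params Named list of overrides for
#'   [simulate_polyA_reads()].
#' @param cohort_params Named list of overrides for [simulate_cohort()].
#' @param droplet_lambda Named vector of true copies/droplet per assay.
#' @param n_droplet_samples Number of ddPCR samples to simulate.
#' @param n_droplets Droplets per assay well.
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, site = oril_site(),
                         read_params = list(),
                         cohort_params = list(),
                         droplet_lambda = c("mt-Co1" = 1.5, "mt-Nd5" = 1.2,
                                            "Vdac1" = 0.3),
                         n_droplet_samples = 8L,
                         n_droplets = 20000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  rp <- utils::modifyList(
    list(site = site,
         allele_fractions = c("9" = 0.03, "10" = 0.07, "11" = 0.65,
                              "12" = 0.20, "13" = 0.05),
         n_reads = 2000L),
    read_params)
  sim <- do.call(simulate_polyA_reads, rp)
  paths <- c(
    sam = file.path(out_dir, "reads.sam"),
    truth = file.path(out_dir, "read_truth.tsv"),
    cohort = file.path(out_dir, "cohort.tsv"),
    droplets = file.path(out_dir, "droplets.tsv"),
    reference = file.path(out_dir, "reference.fa"))
  write_sam(sim$reads, paths["sam"])
  .write_tsv(sim$truth, paths["truth"])
  cohort <- do.call(simulate_cohort, cohort_params)
  .write_tsv(cohort, paths["cohort"])
  drops <- do.call(rbind, lapply(seq_len(n_droplet_samples), function(s) {
    do.call(rbind, lapply(names(droplet_lambda), function(a) {
      dc <- simulate_droplets(droplet_lambda[[a]], n_droplets, assay = a)
      data.frame(sample = sprintf("s%02d", s), assay = a,
                 n_total = dc$n_total, n_negative = dc$n_negative,
                 stringsAsFactors = FALSE)
    }))
  }))
  .write_tsv(drops, paths["droplets"])
  ref <- sim$reference
  writeLines(c(sprintf(">chrM:%d-%d %s", ref$start,
                       ref$start + nchar(ref$seq) - 1L, site$name),
               gsub("(.{70})", "\\1\n", ref$seq)),
             paths["reference"])
  message(sprintf("simulate: seed=%d, %d reads, %d animals, %d ddPCR samples",
                  seed, nrow(sim$reads), nrow(cohort), n_droplet_samples))
  invisible(paths)
}

#' Call heteroplasmy from aligned reads
#'
#' Runs the calling stages in order: quality filter, duplicate marking,
#' motif extraction / pileup, classification. Returns the per-site length
#' spectra, site calls and the filter report; writes them as TSV when
#' `out_dir` is given.
#'
#' @param sam Path to a SAM file or an `aligned_reads` table.
#' @param sites List of [motif_site()] definitions.
#' @param out_dir Optional output directory for `spectrum.tsv`,
#'   `site_calls.tsv` and `filter_report.tsv`.
#' @param sample Sample label written into the outputs.
#' @param min_mean_quality,min_length,require_pair Read filter thresholds
#'   (defaults 30 / 30 / TRUE).
#' @param min_motif_quality Motif mean-quality threshold (default 20).
#' @param min_base_quality Pileup base-quality threshold (default 30).
#' @return A list with `spectra` (data frame: `sample`, `site`,
#'   `run_length`, `count`, `fraction`), `site_calls`, `filter_report`,
#'   and `metrics` (per site, the heteroplasmy aggregates; `NULL` for
#'   empty spectra).
#' @export
run_call_heteroplasmy <- function(sam, sites = list(oril_site()),
                                  out_dir = NULL, sample = "sample1",
                                  min_mean_quality = 30, min_length = 30,
                                  require_pair = TRUE,
                                  min_motif_quality = 20,
                                  min_base_quality = 30) {
  reads <- if (is.character(sam)) parse_sam(sam) else sam
  flt <- filter_reads(reads, min_mean_quality, min_length, require_pair)
  kept <- mark_duplicates(flt$reads)
  report <- rbind(flt$report,
                  data.frame(criterion = "duplicate",
                             n_removed = sum(kept$is_duplicate)))
  report <- rbind(report,
                  data.frame(criterion = "input_total",
                             n_removed = nrow(reads)))
  spectra <- list(); calls <- list(); metrics <- list()
  for (site in sites) {
    obs <- extract_motifs(kept, site, min_motif_quality)
    spec <- count_spectrum(obs, site)
    if (spec$total == 0L) {
      warning("no reads span site ", site$name, "; emitting empty spectrum")
      spectra[[site$name]] <- data.frame(sample = sample, site = site$name,
                                         run_length = NA_integer_,
                                         count = 0L, fraction = NA_real_)
      metrics[site$name] <- list(NULL)
      next
    }
    met <- heteroplasmy_metrics(spec)
    metrics[[site$name]] <- met
    spectra[[site$name]] <- data.frame(sample = sample, site = site$name,
                                       run_length = met$per_length$run_length,
                                       count = met$per_length$count,
                                       fraction = met$per_length$fraction)
    # length-allele call: alternate = any run length other than reference
    alt_len <- 1 - met$ref_fraction
    # point-allele call at the anchor position from the pileup
    pu <- pileup_frequencies(kept, site$anchor_position, min_base_quality)
    ref_base <- site$anchor_base
    pt_row <- if (pu$depth_used > 0L) {
      alts <- pu$frequencies[setdiff(names(pu$frequencies), ref_base)]
      alt_b <- if (length(alts) && max(alts) > 0) names(alts)[which.max(alts)] else NA_character_
      alt_f <- if (length(alts)) max(alts) else 0
      data.frame(sample = sample, site = site$name, kind = "point",
                 position = site$anchor_position, ref = ref_base,
                 alt = alt_b, alt_frequency = alt_f,
                 label = classify_site(alt_f), stringsAsFactors = FALSE)
    } else NULL
    len_row <- data.frame(sample = sample, site = site$name, kind = "length",
                          position = site$anchor_position + 1L,
                          ref = paste0(site$reference_run_length,
                                       site$repeat_base),
                          alt = "other_lengths", alt_frequency = alt_len,
                          label = classify_site(alt_len),
                          stringsAsFactors = FALSE)
    calls[[site$name]] <- rbind(len_row, pt_row)
  }
  out <- list(spectra = do.call(rbind, c(spectra, list(make.row.names = FALSE))),
              site_calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
              filter_report = report, metrics = metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(out$spectra, file.path(out_dir, "spectrum.tsv"))
    if (!is.null(out$site_calls))
      .write_tsv(out$site_calls, file.path(out_dir, "site_calls.tsv"))
    .write_tsv(out$filter_report, file.path(out_dir, "filter_report.tsv"))
  }
  out
}

#' Copy-number step of the pipeline
#'
#' @param droplets Droplet TSV path or data frame
#'   (`sample`, `assay`, `n_total`, `n_negative`).
#' @param out_dir Optional output directory for `copy_ratio.tsv`.
#' @inheritParams copy_ratio_table
#' @return The copy-ratio table.
#' @export
run_copy_number <- function(droplets, out_dir = NULL,
                            numerators = c("mt-Co1", "mt-Nd5"),
                            denominator = "Vdac1") {
  tab <- copy_ratio_table(droplets, numerators, denominator)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(tab, file.path(out_dir, "copy_ratio.tsv"))
  }
  tab
}

#' Cohort analysis step
#'
#' Computes the statistics of a two-strain lifespan cohort: Spearman
#' correlation of heteroplasmy with lifespan (pooled across strains by
#' default, per strain on request) and with copy ratio when present;
#' Kaplan-Meier curves with median and 95% CI per strain; log-rank and
#' Gehan tests between strains; and a Mann-Whitney comparison of
#' heteroplasmy between strains. With a single strain the between-strain
#' tests are skipped with a notice.
#'
#' @param cohort Cohort TSV path or data frame (see [read_cohort_tsv()]).
#' @param out_dir Optional output directory for `stats.tsv` and
#'   `km_curves.tsv`.
#' @param by_strain Also compute the lifespan correlation within each
#'   strain.
#' @return A list with `report` (long data frame: `analysis`, `group`,
#'   `statistic`, `value`, `p`), `km` (per-strain `km_curve` objects) and
#'   `tests`.
#' @export
run_analyze <- function(cohort, out_dir = NULL, by_strain = FALSE) {
  df <- if (is.character(cohort)) read_cohort_tsv(cohort) else cohort
  rows <- list()
  add <- function(analysis, group, statistic, value, p = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, group = group, statistic = statistic,
      value = value, p = p, stringsAsFactors = FALSE)
  }
  sp <- spearman_test(df$het_12A, df$lifespan_days)
  add("spearman_het_lifespan", "pooled", "rho", sp$rho, sp$p)
  if (by_strain) {
    for (s in unique(df$strain)) {
      d <- df[df$strain == s, ]
      if (nrow(d) >= 3L && stats::sd(d$het_12A) > 0) {
        sps <- spearman_test(d$het_12A, d$lifespan_days)
        add("spearman_het_lifespan", s, "rho", sps$rho, sps$p)
      }
    }
  }
  if ("copy_ratio" %in% names(df) && sum(!is.na(df$copy_ratio)) >= 3L) {
    spc <- spearman_test(df$het_12A, df$copy_ratio)
    add("spearman_het_copy_ratio", "pooled", "rho", spc$rho, spc$p)
  }
  km <- list()
  for (s in unique(df$strain)) {
    d <- df[df$strain == s, ]
    if (!any(d$event)) next
    kmc <- km_estimate(d$lifespan_days, d$event)
    km[[s]] <- kmc
    add("km_median", s, "median_days", kmc$median)
    add("km_median", s, "ci_low", kmc$median_ci[1L])
    add("km_median", s, "ci_high", kmc$median_ci[2L])
  }
  tests <- list()
  strains <- unique(df$strain)
  if (length(strains) >= 2L) {
    a <- df[df$strain == strains[1L], ]
    b <- df[df$strain == strains[2L], ]
    lr <- logrank_test(a$lifespan_days, a$event, b$lifespan_days, b$event)
    ge <- gehan_test(a$lifespan_days, a$event, b$lifespan_days, b$event)
    mw <- mann_whitney_u(a$het_12A, b$het_12A)
    tests <- list(logrank = lr, gehan = ge, mann_whitney_het = mw)
    add("logrank_lifespan", paste(strains[1:2], collapse = "_vs_"),
        "chisq", lr$statistic, lr$p)
    add("gehan_lifespan", paste(strains[1:2], collapse = "_vs_"),
        "chisq", ge$statistic, ge$p)
    add("mann_whitney_het", paste(strains[1:2], collapse = "_vs_"),
        "U", mw$U, mw$p)
  } else {
    message("single strain in cohort; between-strain tests skipped")
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(report, file.path(out_dir, "stats.tsv"))
    if (length(km)) {
      curves <- do.call(rbind, lapply(names(km), function(s)
        data.frame(strain = s, time = km[[s]]$times, surv = km[[s]]$surv)))
      .write_tsv(curves, file.path(out_dir, "km_curves.tsv"))
    }
  }
  list(report = report, km = km, tests = tests)
}
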