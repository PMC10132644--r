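# Run-level drivers: one YAML configuration describes a target, a sample
# manifest and analysis toggles; the drivers wire the synthetic-data,
# classification and statistics stages into reproducible runs with
# read-count accounting and a machine-readable manifest.

#' Read and validate a run configuration
#'
#' The configuration is a single YAML file with blocks:
#' \describe{
#'   \item{target}{either `name: geneJ`/`geneL` (the synthetic demo
#'     targets) or the full [target_spec()] fields.}
#'   \item{scenario}{simulation parameters for [run_simulate()]:
#'     `genotypes` (list of haplotype/frequency/weight), `n_generations`,
#'     `pop_size`, `error_rate`, `timepoints`, `replicates`,
#'     `reads_per_sample`, `read_length`, `seq_error_rate`,
#'     `discordance_rate`, `control_replicates`.}
#'   \item{samples}{manifest rows (`sample_id`, `role` =
#'     experimental/control, `timepoint`, `replicate`, `r1`, `r2`) for
#'     [run_amplicon()]; written by [run_simulate()].}
#'   \item{analysis}{toggles: `deletion_convention`, `sd_denominator`,
#'     `require_concordance`, `fix_plateau`.}
#'   \item{seed}{base RNG seed; `output_dir`: where results go.}
#' }
#'
#' @param path YAML configuration path.
#' @return Object of class `run_config` (named list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  cfg$config_md5 <- unname(tools::md5sum(path))
  cfg$seed <- cfg$seed %||% 1L
  cfg$analysis <- cfg$analysis %||% list()
  cfg$analysis$deletion_convention <-
    cfg$analysis$deletion_convention %||% "3prime_adjacent"
  cfg$analysis$sd_denominator <- cfg$analysis$sd_denominator %||% "sample"
  cfg$analysis$require_concordance <-
    cfg$analysis$require_concordance %||% TRUE
  structure(cfg, class = "run_config")
}

config_target_spec <- function(cfg) {
  tg <- cfg$target
  if (!is.null(tg$name)) {
    demo_target_spec(tg$name)
  } else {
    target_spec(tg$amplicon_reference, tg$window_start, tg$window_end,
                pam_side = tg$pam_side %||% "5prime",
                pam_length = tg$pam_length %||% 4L,
                protospacer_length = tg$protospacer_length %||% 20L,
                genome_offset = tg$genome_offset %||% 0L)
  }
}

# stable small derived seed per sample index
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) * 131L + i) %% 2147483647)
}

#' Generate a synthetic escape-experiment fixture bundle
#'
#' Simulates the phage population under the configured selection
#' scenario, samples reads at each timepoint/replicate, and writes paired
#' FASTQ files plus truth tables (planted genotypes and discordant
#' flags) and a sample manifest consumable by [run_amplicon()]. Control
#' samples are drawn from the unselected wild-type-only population with
#' the same sequencing error floor.
#'
#' @param cfg A [read_run_config()] object (or list with the same
#'   fields).
#' @param outdir Output directory (created if needed); defaults to the
#'   config's `output_dir`.
#' @return Invisibly, the sample manifest data.frame (also written as
#'   `samples.tsv`).
#' @export
run_simulate <- function(cfg, outdir = NULL) {
  outdir <- outdir %||% cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_target_spec(cfg)
  sc <- cfg$scenario
  stopifnot(!is.null(sc), !is.null(sc$genotypes))
  refwin <- reference_window(spec)
  g <- do.call(rbind, lapply(sc$genotypes, function(x) {
    hap <- if (identical(x$haplotype, "WT")) refwin else x$haplotype
    data.frame(haplotype = hap, frequency = x$frequency, weight = x$weight,
               stringsAsFactors = FALSE)
  }))
  pool <- genotype_pool(g$haplotype, g$frequency, g$weight)
  series <- simulate_population(pool, sc$n_generations, sc$pop_size,
                                error_rate = sc$error_rate %||% 0,
                                seed = cfg$seed)
  timepoints <- sc$timepoints %||% series$timepoints
  replicates <- sc$replicates %||% 2L
  n_reads <- sc$reads_per_sample %||% 5000L
  manifest <- list()
  truth_all <- list()
  i <- 0L
  emit_one <- function(counts, sample_id, role, tp, rep_i) {
    s <- derive_seed(cfg$seed, i)
    reads <- emit_amplicon_reads(
      counts, spec,
      read_length = sc$read_length %||% 100L,
      seq_error_rate = sc$seq_error_rate %||% 0,
      discordance_rate = sc$discordance_rate %||% 0,
      seed = s
    )
    r1 <- file.path(outdir, paste0(sample_id, "_R1.fastq"))
    r2 <- file.path(outdir, paste0(sample_id, "_R2.fastq"))
    write_fastq(reads$r1, r1)
    write_fastq(reads$r2, r2)
    truth <- reads$truth
    truth$sample_id <- sample_id
    truth_all[[sample_id]] <<- truth
    data.frame(sample_id = sample_id, role = role, timepoint = tp,
               replicate = rep_i, r1 = r1, r2 = r2,
               stringsAsFactors = FALSE)
  }
  for (tp in timepoints) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      counts <- sample_population(series, tp, n_reads,
                                  seed = derive_seed(cfg$seed, 10000L + i))
      manifest[[length(manifest) + 1L]] <-
        emit_one(counts, sprintf("exp_t%s_rep%d", tp, r), "experimental",
                 tp, r)
    }
  }
  ctrl_reps <- sc$control_replicates %||% 2L
  for (r in seq_len(ctrl_reps)) {
    i <- i + 1L
    counts <- stats::setNames(as.integer(n_reads), refwin)
    manifest[[length(manifest) + 1L]] <-
      emit_one(counts, sprintf("ctrl_rep%d", r), "control", NA, r)
  }
  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(outdir, "samples.tsv"))
  write_tsv(do.call(rbind, truth_all), file.path(outdir, "truth.tsv"))
  freq <- series$frequencies
  write_tsv(
    data.frame(haplotype = rownames(freq), freq, check.names = FALSE),
    file.path(outdir, "population_frequencies.tsv")
  )
  write_manifest(cfg, outdir, stage = "simulate")
  invisible(manifest)
}

#' Run the amplicon classification + statistics stages of a configured run
#'
#' For every sample in the manifest: merge read pairs under the
#' concordance rule, classify target windows, tabulate per-position
#' mutated-read proportions, and compute fraction mutated and nucleotide
#' diversity. Then compute positional Z-scores of the experimental
#' samples against the controls and the fraction-mutated time course.
#' All outputs are TSVs; a JSON manifest records the package version,
#' configuration hash and seed. Refuses to run when experimental samples
#' lack a control.
#'
#' @param cfg A [read_run_config()] object.
#' @param outdir Output directory; defaults to the config's
#'   `output_dir`. Sample paths in the manifest may be relative to it.
#' @return Invisibly, a list with the per-sample summary, the Z-score
#'   table and the time-course table.
#' @export
run_amplicon <- function(cfg, outdir = NULL) {
  outdir <- outdir %||% cfg$output_dir
  samples <- cfg$samples
  if (is.null(samples)) {
    sp <- file.path(outdir, "samples.tsv")
    if (!file.exists(sp)) stop("no sample manifest in config or ", outdir)
    samples <- read_tsv(sp)
  } else if (!is.data.frame(samples)) {
    samples <- do.call(rbind, lapply(samples, as.data.frame,
                                     stringsAsFactors = FALSE))
  }
  if (any(samples$role == "experimental") &&
      !any(samples$role == "control")) {
    stop("configuration names experimental samples but no control sample; ",
         "Z-scores need a non-targeted control - add a sample with ",
         "role: control")
  }
  for (p in c(samples$r1, samples$r2)) {
    if (!file.exists(p)) stop("input file missing at run start: ", p)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_target_spec(cfg)
  conv <- cfg$analysis$deletion_convention
  matrices <- list()
  summaries <- list()
  refwin <- reference_window(spec)
  for (k in seq_len(nrow(samples))) {
    s <- samples[k, ]
    r1 <- read_fastq(s$r1)
    r2 <- read_fastq(s$r2)
    merged <- merge_pairs(r1$seq, r2$seq, spec, read_id = r1$id,
                          require_concordance = cfg$analysis$require_concordance)
    calls <- classify_reads(merged, spec)
    write_tsv(calls[, c("read_id", "status", "variant_class", "labels")],
              file.path(outdir, paste0(s$sample_id, "_classification.tsv")))
    pm <- tabulate_variants(calls, spec, sample_id = s$sample_id,
                            deletion_convention = conv)
    matrices[[s$sample_id]] <- pm
    ht <- haplotype_table(calls)
    div <- nucleotide_diversity(ht$haplotype, ht$frequency,
                                L = nchar(refwin), reference = refwin)
    counts <- table(factor(calls$status,
                           levels = c("accepted", "rejected_discordant",
                                      "rejected_unalignable")))
    message(sprintf(
      "[%s] %d pairs: %d accepted, %d discordant, %d unalignable",
      s$sample_id, nrow(calls), counts[["accepted"]],
      counts[["rejected_discordant"]], counts[["rejected_unalignable"]]))
    summaries[[k]] <- data.frame(
      sample_id = s$sample_id, role = s$role, timepoint = s$timepoint,
      replicate = s$replicate,
      n_pairs = nrow(calls),
      n_accepted = counts[["accepted"]],
      n_discordant = counts[["rejected_discordant"]],
      n_unalignable = counts[["rejected_unalignable"]],
      fraction_mutated = fraction_mutated(calls),
      diversity = div,
      stringsAsFactors = FALSE
    )
    mat_df <- data.frame(index = pm$positions,
                         proportion = unname(pm$proportions))
    write_tsv(mat_df, file.path(outdir, paste0(s$sample_id, "_positions.tsv")))
  }
  summary_df <- do.call(rbind, summaries)
  write_tsv(summary_df, file.path(outdir, "sample_summary.tsv"))
  z <- NULL
  if (any(samples$role == "experimental")) {
    z <- zscores(matrices[samples$sample_id[samples$role == "experimental"]],
                 matrices[samples$sample_id[samples$role == "control"]],
                 sd_denominator = cfg$analysis$sd_denominator)
    write_tsv(as.data.frame(z), file.path(outdir, "zscores.tsv"))
  }
  tc <- NULL
  exp_s <- summary_df[summary_df$role == "experimental", , drop = FALSE]
  if (nrow(exp_s)) {
    tps <- sort(unique(exp_s$timepoint))
    rows <- lapply(tps, function(tp) {
      fr <- exp_s$fraction_mutated[exp_s$timepoint == tp]
      data.frame(time = tp, mean_fraction = mean(fr),
                 sd_fraction = if (length(fr) > 1) stats::sd(fr) else NA_real_,
                 n_replicates = length(fr))
    })
    tc <- do.call(rbind, rows)
    write_tsv(tc, file.path(outdir, "timecourse.tsv"))
  }
  write_manifest(cfg, outdir, stage = "amplicon")
  invisible(list(samples = summary_df, zscores = z, timecourse = tc))
}

write_manifest <- function(cfg, outdir, stage) {
  manifest <- list(
    stage = stage,
    package = "crisprEscape",
    version = as.character(utils::packageVersion("crisprEscape")),
    config_md5 = cfg$config_md5 %||% NA_character_,
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Render run figures: Z-score heat map and fraction-mutated time course
#'
#' Minimal analogues of the published presentation: a white-to-red tile
#' map of Z by PAM-relative position (colour ceiling at the data
#' maximum) and a line chart of mean fraction mutated over time with SD
#' error bars.
#'
#' @param outdir A completed [run_amplicon()] output directory.
#' @return Invisibly, paths of the written PNG files.
#' @export
render_report <- function(outdir) {
  written <- character()
  zp <- file.path(outdir, "zscores.tsv")
  if (file.exists(zp)) {
    z <- read_tsv(zp)
    zdf <- data.frame(position = factor(z$index, levels = z$index),
                      sample = "experimental vs control",
                      z_pos = pmax(z$z, 0))
    zmax <- max(zdf$z_pos, 0)
    p <- ggplot2::ggplot(zdf, ggplot2::aes(
      x = position, y = sample, fill = z_pos)) +
      ggplot2::geom_tile(colour = "grey70") +
      ggplot2::scale_fill_gradient(low = "white", high = "red",
                                   limits = c(0, max(zmax, 1e-9)),
                                   name = "Z") +
      ggplot2::labs(x = "position (PAM-relative)", y = NULL) +
      ggplot2::theme_minimal()
    f <- file.path(outdir, "zscore_heatmap.png")
    ggplot2::ggsave(f, p, width = 8, height = 2, dpi = 120)
    written <- c(written, f)
  }
  tp <- file.path(outdir, "timecourse.tsv")
  if (file.exists(tp)) {
    tc <- read_tsv(tp)
    p <- ggplot2::ggplot(tc, ggplot2::aes(time, mean_fraction)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = pmax(mean_fraction - sd_fraction, 0),
        ymax = pmin(mean_fraction + sd_fraction, 1)), width = 0.1) +
      ggplot2::scale_y_continuous(limits = c(0, 1)) +
      ggplot2::labs(x = "time (generations)", y = "fraction mutated") +
      ggplot2::theme_classic()
    f <- file.path(outdir, "fraction_mutated.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
    written <- c(written, f)
  }
  invisible(written)
}
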