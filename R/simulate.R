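# Run expr under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulator configuration
#'
#' Defines the synthetic cfDNA data-generating process: a toy binned genome
#' (22 autosomes x `n_bins_autosome` bins, plus X and Y), shallow shotgun
#' depth, negative-binomial count noise, per-sample GC bias, and the
#' maternal/fetal mixture model. Defaults emulate the production conditions:
#' 50 kb bins, 1.2e7 reads/sample, plates of 12, fetal fraction drawn from
#' U(0.08, 0.15), and count dispersion calibrated so the euploid
#' chromosome-representation robust CV stays at or below 0.3% at default
#' depth. GC fractions are Beta(14, 21) (mean ~0.4) with chromosomes 13 and
#' 18 shifted GC-rich so that GC bias skews their representations, as it
#' does in real data.
#'
#' @param ... Named overrides.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_bins_autosome = 100,
    n_bins_x = 100,
    n_bins_y = 20,
    bin_size = 5e4,
    depth = 1.2e7,
    nb_size = 5000,
    gc_center = 0.40,
    gc_bias_mean = 0,
    gc_bias_sd = 0.4,
    gc_shift = c("13" = 0.07, "18" = 0.04),
    y_background = 0.02,
    ff_range = c(0.08, 0.15),
    samples_per_plate = 12,
    genome_seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "sim_config")
}

#' Build the simulated genome
#'
#' Generates the bin set (with GC fractions) and the per-bin Y-chromosome
#' behaviour: the first two Y bins are pseudoautosomal-like (female signal
#' equal to male, so they fail the fivefold selection rule), the third is
#' low-mappability (male signal below the 150-read rule), the rest are
#' Y-specific with a small mis-mapping background in females.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome`: list with `bins` ([bin_set]) and per-Y-bin rate
#'   vectors `y_specific`, `y_female_bg`.
#' @export
sim_genome <- function(config = sim_config()) {
  with_seed(config$genome_seed, {
    chroms <- c(rep(AUTOSOMES, each = config$n_bins_autosome),
                rep("X", config$n_bins_x), rep("Y", config$n_bins_y))
    n <- length(chroms)
    start <- unlist(lapply(table(factor(chroms, levels = unique(chroms))),
                           function(k) (seq_len(k) - 1) * config$bin_size),
                    use.names = FALSE)
    gc <- stats::rbeta(n, 14, 21)
    for (ch in names(config$gc_shift)) {
      gc[chroms == ch] <- gc[chroms == ch] + config$gc_shift[[ch]]
    }
    gc <- pmin(pmax(gc, 0.05), 0.95)
    bins <- bin_set(chroms, start, start + config$bin_size, gc)
    ny <- config$n_bins_y
    y_kind <- c(rep("PAR", min(2, ny)), rep("LOWMAP", min(1, max(ny - 2, 0))),
                rep("SPECIFIC", max(ny - 3, 0)))
    structure(list(bins = bins, config = config, y_kind = y_kind),
              class = "sim_genome")
  })
}

#' Specify one simulation scenario
#'
#' @param n Number of samples.
#' @param aneuploidy `"EUPLOID"`, `"T13"`, `"T18"` or `"T21"`.
#' @param sex Fetal sex karyotype(s) to draw from: subset of
#'   `c("XX","XY","X","XXX","XXY","XYY")`. Ignored for adult subjects.
#' @param ff Fetal fraction: `NULL` (draw from the config range), a single
#'   value, or a range `c(lo, hi)`.
#' @param mosaic Fraction of trisomic fetal cells (1 = non-mosaic).
#' @param subject `"PREGNANT"`, `"ADULT_FEMALE"` or `"ADULT_MALE"`
#'   (non-pregnant controls; `ff` is forced to 0).
#' @param maternal_dup Maternal segmental duplication, encoded
#'   `"chrom:lo-hi:copies"` with lo/hi fractional positions along the
#'   chromosome (e.g. `"21:0.2-0.3:3"`), or `NA`.
#' @param fetal_cnv Fetal segmental copy-number event in the same encoding
#'   (e.g. a heterozygous DiGeorge-like deletion `"22:0.4-0.6:1"`), or `NA`.
#' @param global_ab Global maternal copy-number aberration, encoded
#'   `"chrom:delta;chrom:delta"` where delta is the effective copy shift
#'   (e.g. `"3:0.9;4:-0.9"`), or `NA`.
#' @param twin For twin gestations: list with `ff2`, `aneuploidy2`, `sex2`.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n, aneuploidy = "EUPLOID", sex = c("XX", "XY"),
                         ff = NULL, mosaic = 1, subject = "PREGNANT",
                         maternal_dup = NA, global_ab = NA, fetal_cnv = NA,
                         twin = NULL) {
  stopifnot(aneuploidy %in% c("EUPLOID", "T13", "T18", "T21"),
            subject %in% c("PREGNANT", "ADULT_FEMALE", "ADULT_MALE"))
  list(n = n, aneuploidy = aneuploidy, sex = sex, ff = ff, mosaic = mosaic,
       subject = subject, maternal_dup = maternal_dup, global_ab = global_ab,
       fetal_cnv = fetal_cnv, twin = twin)
}

draw_ff <- function(spec, config) {
  if (is.null(spec)) stats::runif(1, config$ff_range[1], config$ff_range[2])
  else if (length(spec) == 2) stats::runif(1, spec[1], spec[2])
  else spec
}

#' Build a truth table from scenarios
#'
#' Assigns sample ids, draws fetal sex and fetal fraction, shuffles samples
#' and lays them out on plates of `samples_per_plate`.
#'
#' @param scenarios List of [sim_scenario()] specs.
#' @param config A [sim_config()].
#' @return `data.frame` of per-sample ground truth.
#' @export
build_truth <- function(scenarios, config = sim_config()) {
  rows <- list()
  for (sc in scenarios) {
    for (k in seq_len(sc$n)) {
      adult <- sc$subject != "PREGNANT"
      sex <- if (adult) "" else sample(sc$sex, 1)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = NA_character_, plate = NA_character_,
        subject = sc$subject,
        aneuploidy = sc$aneuploidy,
        sex_karyotype = sex,
        ff = if (adult) 0 else draw_ff(sc$ff, config),
        mosaic = sc$mosaic,
        twin_ff2 = if (is.null(sc$twin)) NA_real_ else sc$twin$ff2,
        twin_aneuploidy2 = if (is.null(sc$twin)) NA_character_ else sc$twin$aneuploidy2,
        twin_sex2 = if (is.null(sc$twin)) NA_character_ else sc$twin$sex2,
        maternal_dup = sc$maternal_dup,
        global_ab = sc$global_ab,
        fetal_cnv = sc$fetal_cnv,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
  truth$sample_id <- sprintf("S%04d", seq_len(nrow(truth)))
  truth$plate <- sprintf("P%03d",
                         (seq_len(nrow(truth)) - 1) %/% config$samples_per_plate + 1)
  rownames(truth) <- NULL
  truth
}

# Copy numbers per bin for one genome contributor.
contributor_copies <- function(genome, aneuploidy, sex_karyotype, mosaic = 1) {
  bins <- genome$bins
  copies <- ifelse(bins$chrom %in% AUTOSOMES, 2, 0)
  if (aneuploidy != "EUPLOID") {
    target <- sub("T", "", aneuploidy)
    copies[bins$chrom == target] <- 2 + mosaic
  }
  x_copies <- switch(sex_karyotype,
                     XX = 2, XY = 1, X = 1, XXX = 3, XXY = 2, XYY = 1, 2)
  y_copies <- switch(sex_karyotype,
                     XY = 1, XXY = 1, XYY = 2, 0)
  copies[bins$chrom == "X"] <- x_copies
  copies[bins$chrom == "Y"] <- y_copies
  copies
}

parse_maternal_dup <- function(spec) {
  p <- strsplit(spec, ":")[[1]]
  span <- as.numeric(strsplit(p[2], "-")[[1]])
  list(chrom = p[1], lo = span[1], hi = span[2], copies = as.numeric(p[3]))
}

parse_global_ab <- function(spec) {
  parts <- strsplit(spec, ";")[[1]]
  out <- lapply(parts, function(s) {
    p <- strsplit(s, ":")[[1]]
    list(chrom = p[1], delta = as.numeric(p[2]))
  })
  out
}

maternal_copies <- function(genome, truth_row) {
  sexk <- if (truth_row$subject == "ADULT_MALE") "XY" else "XX"
  copies <- contributor_copies(genome, "EUPLOID", sexk)
  bins <- genome$bins
  if (!is.na(truth_row$maternal_dup)) {
    d <- parse_maternal_dup(truth_row$maternal_dup)
    idx <- which(bins$chrom == d$chrom)
    pos <- (seq_along(idx) - 0.5) / length(idx)
    copies[idx[pos >= d$lo & pos < d$hi]] <- d$copies
  }
  if (!is.na(truth_row$global_ab)) {
    for (g in parse_global_ab(truth_row$global_ab)) {
      copies[bins$chrom == g$chrom] <- copies[bins$chrom == g$chrom] + g$delta
    }
  }
  copies
}

#' Expected per-bin read counts for one sample
#'
#' The deterministic mean structure of the simulator, before count noise:
#' bin mean = depth x share(bin), with share proportional to
#' `copy_mix(bin) / 2 x gc_bias(gc)` and
#' `copy_mix = (1 - f [- f2]) x maternal + f x fetal [+ f2 x fetal2]`. Y
#' bins add the mis-mapping background; pseudoautosomal-like Y bins behave
#' autosomally and the low-mappability Y bin is attenuated.
#'
#' @param genome A [sim_genome()].
#' @param truth_row One row of the truth table.
#' @param gc_beta The sample's GC-bias slope (0 = unbiased).
#' @return Numeric vector of expected counts per bin.
#' @export
expected_bin_means <- function(genome, truth_row, gc_beta = 0) {
  config <- genome$config
  bins <- genome$bins
  f <- truth_row$ff
  f2 <- if (!is.na(truth_row$twin_ff2)) truth_row$twin_ff2 else 0
  if (f + f2 > 0.5) stop("twin fetal fractions sum above 0.5")
  m <- maternal_copies(genome, truth_row)
  c1 <- contributor_copies(genome, truth_row$aneuploidy,
                           truth_row$sex_karyotype, truth_row$mosaic)
  if (!is.na(truth_row$fetal_cnv)) {
    d <- parse_maternal_dup(truth_row$fetal_cnv)
    idx <- which(bins$chrom == d$chrom)
    pos <- (seq_along(idx) - 0.5) / length(idx)
    c1[idx[pos >= d$lo & pos < d$hi]] <- d$copies
  }
  mix <- (1 - f - f2) * m + f * c1
  if (f2 > 0) {
    c2 <- contributor_copies(genome, truth_row$twin_aneuploidy2,
                             truth_row$twin_sex2, truth_row$mosaic)
    mix <- mix + f2 * c2
  }
  rate <- mix / 2
  y_idx <- which(bins$chrom == "Y")
  rate[y_idx][genome$y_kind == "PAR"] <- 1
  rate[y_idx][genome$y_kind == "LOWMAP"] <-
    0.02 * rate[y_idx][genome$y_kind == "LOWMAP"] / 0.5 + 0.002
  rate[y_idx][genome$y_kind == "SPECIFIC"] <-
    rate[y_idx][genome$y_kind == "SPECIFIC"] + config$y_background
  gcf <- pmax(1 + gc_beta * (bins$gc - config$gc_center), 0.05)
  rate <- rate * gcf
  config$depth * rate / sum(rate)
}

#' Simulate one sample's bin counts
#'
#' Draws the sample's GC-bias slope from `N(gc_bias_mean, gc_bias_sd)` and
#' negative-binomial counts around [expected_bin_means()] at dispersion
#' `nb_size`. Uses the current RNG stream (seed at the cohort level).
#'
#' @param genome A [sim_genome()].
#' @param truth_row One truth-table row.
#' @return Integer vector of bin counts.
#' @export
simulate_sample <- function(genome, truth_row) {
  config <- genome$config
  beta <- stats::rnorm(1, config$gc_bias_mean, config$gc_bias_sd)
  mu <- expected_bin_means(genome, truth_row, gc_beta = beta)
  stats::rnbinom(length(mu), mu = mu, size = config$nb_size)
}

#' Simulate a cohort with known truth
#'
#' Fully determined by `seed`: builds the truth table from the scenario
#' list, simulates every sample, and returns counts, truth and the genome.
#'
#' @param scenarios List of [sim_scenario()] specs.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_cohort`: list with `counts` ([count_matrix]), `truth`,
#'   `genome` and `bins`.
#' @export
simulate_cohort <- function(scenarios, config = sim_config(), seed = 1) {
  genome <- sim_genome(config)
  with_seed(seed, {
    truth <- build_truth(scenarios, config)
    counts <- t(vapply(seq_len(nrow(truth)), function(i) {
      simulate_sample(genome, truth[i, ])
    }, numeric(nrow(genome$bins))))
    dimnames(counts) <- list(truth$sample_id, rownames(genome$bins))
    cm <- count_matrix(counts, data.frame(sample_id = truth$sample_id,
                                          plate = truth$plate,
                                          stringsAsFactors = FALSE))
    structure(list(counts = cm, truth = truth, genome = genome,
                   bins = genome$bins), class = "sim_cohort")
  })
}

#' Plant a learnable fetal-fraction signal in autosomal bins
#'
#' Real cfDNA carries fetal-fraction-correlated autosomal count structure
#' (fragment-length and coverage effects) that the female-fetus regression
#' model exploits; the simulator's mixture model alone has none, so this
#' helper adds an explicit low-rank perturbation: a fixed +/- pattern over a
#' random subset of bins outside chromosomes 13/18/21/X/Y, scaled per sample
#' by a latent variable correlated with the true fetal fraction at the given
#' `strength`. This is a simulator construct, not a claim about the
#' biological mechanism.
#'
#' @param cohort A `sim_cohort`.
#' @param strength Target correlation between the latent scale and true FF,
#'   in `[0, 1]`; 0 leaves the cohort unchanged.
#' @param n_bins Number of perturbed bins (default 200).
#' @param amp Relative amplitude per unit latent (default 0.05).
#' @param seed Seed for the bin pattern and latent noise.
#' @return The cohort with modified counts.
#' @export
plant_female_ff_signal <- function(cohort, strength, n_bins = 200,
                                   amp = 0.05, seed = 1) {
  stopifnot(strength >= 0, strength <= 1)
  if (strength == 0) return(cohort)
  bins <- cohort$bins
  allowed <- which(bins$chrom %in% setdiff(AUTOSOMES, c("13", "18", "21")))
  with_seed(seed + 7L, {
    sel <- sample(allowed, min(n_bins, length(allowed)))
    v <- sample(c(-1, 1), length(sel), replace = TRUE)
    ff <- cohort$truth$ff
    z <- (ff - mean(ff)) / stats::sd(ff)
    latent <- strength * z + sqrt(1 - strength^2) * stats::rnorm(length(ff))
    counts <- cohort$counts$counts
    for (i in seq_along(latent)) {
      fac <- pmax(1 + amp * latent[i] * v, 0.05)
      counts[i, sel] <- round(counts[i, sel] * fac)
    }
    cohort$counts$counts <- counts
    cohort
  })
}

#' Write / read a simulated cohort as plain text
#'
#' Emits `bins.bed`, `counts.tsv`, `truth.tsv` and `config.yaml` into a
#' directory; `load_cohort` round-trips them.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bins(cohort$bins, file.path(dir, "bins.bed"))
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cohort$genome$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  config <- do.call(sim_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(sample_id = "character",
                                            plate = "character"))
  structure(list(counts = load_counts(file.path(dir, "counts.tsv")),
                 truth = truth,
                 genome = sim_genome(config),
                 bins = load_bins(file.path(dir, "bins.bed"))),
            class = "sim_cohort")
}
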