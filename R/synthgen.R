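# ---------------------------------------------------------------------------
# Synthetic-data generators emulating the study designs.
#
# All generators are pure functions of their arguments plus a seed: randomness
# goes through a local RNG scope so global .Random.seed is untouched and the
# same call always returns byte-identical output.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Factorial microarray simulation design
#'
#' Describes the pooled 2x2x2 factorial array layout: `arrays_per_cell` arrays
#' in each Sex (M/F) x Diet (LPD/CTRL) x Stress (swim/none) cell, each array
#' hybridized with a pool of `pool_size` animals, plus a male-only technical
#' replication batch of `replication_arrays` arrays (spread over the four male
#' cells). The defaults reproduce the 16-array main experiment (32 animals
#' pooled two by two) with an 8-array male replication batch.
#'
#' @param n_probes number of probes on the array.
#' @param arrays_per_cell arrays per factorial cell in the main batch.
#' @param pool_size animals pooled per array.
#' @param replication_arrays total arrays in the male-only replication batch;
#'   must be a multiple of 4 (the number of male cells).
#' @return an object of class `sim_design` with the per-array sample sheet.
#' @export
sim_design <- function(n_probes = 60000L, arrays_per_cell = 2L,
                       pool_size = 2L, replication_arrays = 8L) {
  stopifnot(n_probes >= 1, arrays_per_cell >= 1, pool_size >= 1,
            replication_arrays >= 0, replication_arrays %% 4 == 0)
  cells <- expand.grid(sex = c("F", "M"), diet = c("CTRL", "LPD"),
                       stress = c("none", "swim"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  main <- cells[rep(seq_len(nrow(cells)), each = arrays_per_cell), ]
  main$batch <- "main"
  male_cells <- cells[cells$sex == "M", ]
  rep_per_cell <- replication_arrays %/% 4L
  repl <- male_cells[rep(seq_len(nrow(male_cells)), each = rep_per_cell), ]
  if (nrow(repl)) repl$batch <- "replication"
  sheet <- rbind(main, if (nrow(repl)) repl)
  sheet$sample_id <- sprintf("%s_%02d", ifelse(sheet$batch == "main", "A", "R"),
                             stats::ave(seq_len(nrow(sheet)), sheet$batch,
                                        FUN = seq_along))
  rownames(sheet) <- sheet$sample_id
  structure(list(n_probes = as.integer(n_probes),
                 arrays_per_cell = as.integer(arrays_per_cell),
                 pool_size = as.integer(pool_size),
                 replication_arrays = as.integer(replication_arrays),
                 samples = sheet[, c("sample_id", "sex", "diet", "stress", "batch")]),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Factorial microarray simulation design\n")
  cat(sprintf("  %d probes; %d main arrays (%d per cell, pools of %d); %d replication arrays (male only)\n",
              x$n_probes, sum(x$samples$batch == "main"), x$arrays_per_cell,
              x$pool_size, x$replication_arrays))
  invisible(x)
}

#' Spike-in effect specification
#'
#' Declares a set of probes carrying a log2-scale shift for one design factor
#' (optionally an interaction of two factors). Used as ground truth for
#' recovery testing of the differential expression screen.
#'
#' @param probes integer or character probe identifiers.
#' @param factor one of `"sex"`, `"diet"`, `"stress"`.
#' @param log2_effect signed effect in log2 units (level 2 minus level 1,
#'   where level order is F<M, CTRL<LPD, none<swim).
#' @param interaction optional second factor; the effect is then applied to
#'   the (level-2, level-2) cell only.
#' @export
effect_spec <- function(probes, factor, log2_effect, interaction = NULL) {
  stopifnot(is.finite(log2_effect),
            factor %in% c("sex", "diet", "stress"),
            is.null(interaction) || interaction %in% c("sex", "diet", "stress"))
  structure(list(probes = probes, factor = factor,
                 log2_effect = log2_effect, interaction = interaction),
            class = "effect_spec")
}

#' Technical + biological noise model for expression simulation
#'
#' Per-probe technical variances are drawn from a scaled inverse chi-square
#' prior `s0_sq * d0 / chisq(d0)` (the distribution the moderated-statistics
#' machinery assumes); animals add iid biological noise with sd `bio_sd`
#' (halved in variance by pooling two animals per array); a rank-1
#' array-score x probe-loading term injects a dominant technical component so
#' that the first principal component of the simulated matrix is the batch
#' axis by construction. `batch_frac` sets the expected share of per-probe
#' array-level variance attributable to that component.
#'
#' @param d0 prior degrees of freedom (> 0, may be `Inf`).
#' @param s0_sq prior variance, (log2 units)^2.
#' @param bio_sd per-animal biological sd, log2 units.
#' @param batch_frac fraction of array-level variance carried by the rank-1
#'   technical component, in [0, 1).
#' @export
noise_model <- function(d0 = 4, s0_sq = 0.04, bio_sd = 0.25, batch_frac = 0.4) {
  stopifnot(d0 > 0, s0_sq >= 0, bio_sd >= 0, batch_frac >= 0, batch_frac < 1)
  structure(list(d0 = d0, s0_sq = s0_sq, bio_sd = bio_sd,
                 batch_frac = batch_frac), class = "noise_model")
}

cell_effect_matrix <- function(samples, effects, n_probes) {
  # probe x sample matrix of deterministic effect contributions
  eff <- matrix(0, n_probes, nrow(samples))
  lvl2 <- c(sex = "M", diet = "LPD", stress = "swim")
  seen <- list()
  for (e in effects) {
    key <- paste(e$factor, e$interaction %||% "", sep = ":")
    idx <- if (is.character(e$probes)) match(e$probes, rownames(eff)) else e$probes
    prev <- seen[[key]]
    if (any(idx %in% prev)) {
      stop("overlapping effect specs for the same probe and factor(s): ", key)
    }
    seen[[key]] <- c(prev, idx)
    on_col <- samples[[e$factor]] == lvl2[[e$factor]]
    if (!is.null(e$interaction)) {
      on_col <- on_col & samples[[e$interaction]] == lvl2[[e$interaction]]
    }
    eff[idx, on_col] <- eff[idx, on_col] + e$log2_effect
  }
  eff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a pooled factorial expression experiment
#'
#' Generates log2 probe intensities for the main and replication batches as
#' baseline + design effects + rank-1 technical component + noise. Each array
#' value is the average of `pool_size` animal-level draws (baseline + effects
#' + biological noise), matching the pooled hybridization design, plus
#' array-level technical noise with probe variance drawn from the scaled
#' inverse chi-square prior of `noise`.
#'
#' @param design a [sim_design()].
#' @param effects list of [effect_spec()] objects (spike-in truth).
#' @param noise a [noise_model()].
#' @param seed integer seed; fully determines the output.
#' @param baseline_range baseline log2 intensity range (uniform per probe).
#' @param dead_fraction fraction of probes simulated as dead/unexpressed (at
#'   background level, the population the low-signal filter removes); dead
#'   probes are drawn outside any spiked set and carry no effects.
#' @param background_level log2 intensity of dead probes.
#' @return an `expression_experiment`: list with `matrix` (probe x sample),
#'   `samples` sheet, and a `truth` list (spiked probe table, per-probe
#'   technical variances, batch scores/loadings, dead probes).
#' @export
simulate_expression <- function(design, effects = list(), noise = noise_model(),
                                seed = 1L, baseline_range = c(6, 14),
                                dead_fraction = 0.05, background_level = 2) {
  stopifnot(inherits(design, "sim_design"), inherits(noise, "noise_model"))
  samples <- design$samples
  G <- design$n_probes
  n <- nrow(samples)
  with_seed(seed, {
    probe_ids <- sprintf("P%06d", seq_len(G))
    baseline <- stats::runif(G, baseline_range[1], baseline_range[2])
    eff <- cell_effect_matrix(samples, effects, G)
    rownames(eff) <- probe_ids
    dead <- integer(0)
    if (dead_fraction > 0) {
      live_effects <- which(rowSums(abs(eff)) > 0)
      pool <- setdiff(seq_len(G), live_effects)
      dead <- sample(pool, round(dead_fraction * G))
      baseline[dead] <- background_level
    }
    # per-probe technical variance from scaled inverse chi-square prior
    s2_tech <- if (is.finite(noise$d0)) {
      noise$s0_sq * noise$d0 / stats::rchisq(G, df = noise$d0)
    } else rep(noise$s0_sq, G)
    # pooled animal draws: biological noise variance shrinks by pool size
    bio_var <- noise$bio_sd^2 / design$pool_size
    tot_var <- bio_var + s2_tech
    mat <- baseline + eff
    if (any(tot_var > 0)) {
      mat <- mat + matrix(stats::rnorm(G * n, sd = sqrt(tot_var)), G, n)
    }
    scores <- loadings <- NULL
    if (noise$batch_frac > 0) {
      # the technical component is a property of the main hybridization
      # batch (the replication ran on separate hardware); scores are zero
      # for replication arrays
      f <- noise$batch_frac
      scores <- ifelse(samples$batch == "main", stats::rnorm(n), 0)
      loadings <- stats::rnorm(G, sd = sqrt(f / (1 - f) * mean(tot_var)))
      mat <- mat + tcrossprod(loadings, scores)
    }
    dimnames(mat) <- list(probe_ids, samples$sample_id)
    spiked <- if (length(effects)) {
      do.call(rbind, lapply(effects, function(e) {
        data.frame(probe = if (is.character(e$probes)) e$probes else probe_ids[e$probes],
                   factor = e$factor,
                   interaction = e$interaction %||% NA_character_,
                   log2_effect = e$log2_effect)
      }))
    } else {
      data.frame(probe = character(), factor = character(),
                 interaction = character(), log2_effect = numeric())
    }
    structure(list(matrix = mat, samples = samples, probe_ids = probe_ids,
                   truth = list(spiked = spiked, s2_tech = s2_tech,
                                total_var = tot_var,
                                batch_scores = scores, batch_loadings = loadings,
                                dead_probes = probe_ids[dead],
                                baseline = baseline)),
              class = "expression_experiment")
  })
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf("expression_experiment: %d probes x %d arrays (%d main, %d replication), %d spiked probes\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$samples$batch == "main"),
              sum(x$samples$batch == "replication"), nrow(x$truth$spiked)))
  invisible(x)
}

#' Simulate replicate ChIP peak-call interval sets
#'
#' Produces one interval set per replicate sample on a toy contig: each true
#' locus appears in a sample with probability `presence_prob`, with start/end
#' jittered by Gaussian noise (clamped at 0); spurious noise peaks arrive as a
#' Poisson process along the contig; an input-control set passes through
#' unchanged. Coordinates are 0-based half-open throughout.
#'
#' @param n_samples number of replicate samples.
#' @param true_loci data.frame with columns `contig`, `start`, `end`.
#' @param presence_prob per-sample inclusion probability of each true locus.
#' @param jitter_sd sd (bp) of boundary jitter.
#' @param noise_rate expected spurious peaks per megabase per sample.
#' @param input_loci data.frame of input-control artifact intervals (may have
#'   zero rows).
#' @param contig_length toy contig length in bp.
#' @param noise_width width (bp) of spurious peaks.
#' @param seed integer seed.
#' @return a `peak_collection_set`: list of per-sample interval data.frames
#'   (`contig`, `start`, `end`), the `input` collection, and a `truth` table.
#' @export
simulate_peaksets <- function(n_samples, true_loci, presence_prob = 1,
                              jitter_sd = 0, noise_rate = 0,
                              input_loci = empty_peaks(), contig_length = 1e6,
                              noise_width = 200L, seed = 1L) {
  stopifnot(n_samples >= 1, presence_prob >= 0, presence_prob <= 1,
            jitter_sd >= 0, noise_rate >= 0)
  true_loci <- as_peaks(true_loci)
  input_loci <- as_peaks(input_loci)
  stopifnot(all(true_loci$start >= 0), all(input_loci$start >= 0))
  with_seed(seed, {
    samples <- lapply(seq_len(n_samples), function(i) {
      keep <- stats::runif(nrow(true_loci)) < presence_prob
      loci <- true_loci[keep, , drop = FALSE]
      if (nrow(loci) && jitter_sd > 0) {
        loci$start <- pmax(0, round(loci$start + stats::rnorm(nrow(loci), sd = jitter_sd)))
        loci$end <- round(loci$end + stats::rnorm(nrow(loci), sd = jitter_sd))
        loci$end <- pmax(loci$end, loci$start + 1)  # keep width >= 1
      }
      n_noise <- stats::rpois(1, noise_rate * contig_length / 1e6)
      if (n_noise > 0) {
        st <- floor(stats::runif(n_noise, 0, max(contig_length - noise_width, 1)))
        loci <- rbind(loci, data.frame(contig = if (nrow(true_loci)) true_loci$contig[1] else "chrT",
                                       start = st, end = st + noise_width))
      }
      normalize_peaks(loci)
    })
    names(samples) <- sprintf("rep%02d", seq_len(n_samples))
    structure(list(samples = samples, input = normalize_peaks(input_loci),
                   truth = true_loci, contig_length = contig_length),
              class = "peak_collection_set")
  })
}

#' Simulate per-animal per-CpG percent methylation tables
#'
#' Emulates bisulfite pyrosequencing output for a Sex x Diet design: each
#' animal gets a random intercept shared by all CpGs of an assay (the repeated
#' measure), an optional Sex x Diet interaction effect confined to intron
#' assays (added to the LPD-female cell), and iid residual noise. Values are
#' clamped to [0, 100].
#'
#' @param n_per_cell animals per Sex x Diet cell.
#' @param assays character vector of assay names; names containing "intron"
#'   receive the interaction effect.
#' @param cpgs_per_assay CpG positions per assay.
#' @param baseline_pct baseline percent methylation (may be a named vector per
#'   assay).
#' @param animal_sd sd of the per-animal (x assay) random intercept.
#' @param residual_sd residual sd.
#' @param interaction_effect_pct percent added to the (LPD, F) cell in intron
#'   assays.
#' @param seed integer seed.
#' @return a `methylation_table` data.frame with columns `animal_id`, `sex`,
#'   `diet`, `assay`, `cpg`, `pct`, plus a `truth` attribute.
#' @export
simulate_methylation <- function(n_per_cell = 12L,
                                 assays = c("promoter", "intron1a", "intron1b", "B1", "IAP"),
                                 cpgs_per_assay = 5L, baseline_pct = 5,
                                 animal_sd = 1, residual_sd = 1,
                                 interaction_effect_pct = 0, seed = 1L) {
  stopifnot(all(baseline_pct >= 0), all(baseline_pct <= 100), n_per_cell >= 1)
  cells <- expand.grid(sex = c("F", "M"), diet = c("CTRL", "LPD"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  animals <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  animals$animal_id <- sprintf("a%03d", seq_len(nrow(animals)))
  base <- if (length(baseline_pct) == 1) stats::setNames(rep(baseline_pct, length(assays)), assays)
          else baseline_pct[assays]
  with_seed(seed, {
    rows <- list()
    for (as_name in assays) {
      intercepts <- stats::rnorm(nrow(animals), sd = animal_sd)
      eff <- if (grepl("intron", as_name))
        interaction_effect_pct * (animals$diet == "LPD" & animals$sex == "F") else 0
      for (k in seq_len(cpgs_per_assay)) {
        v <- base[[as_name]] + eff + intercepts +
          stats::rnorm(nrow(animals), sd = residual_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animals$animal_id, sex = animals$sex, diet = animals$diet,
          assay = as_name, cpg = k, pct = pmin(100, pmax(0, v)))
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    structure(tab, class = c("methylation_table", "data.frame"),
              truth = list(interaction_effect_pct = interaction_effect_pct,
                           intron_assays = assays[grepl("intron", assays)],
                           baseline = base))
  })
}

#' Simulate a qPCR Ct table with two housekeeping genes
#'
#' Target Cts are a gene-specific base cycle plus declared per-factor shifts
#' (in cycles; negative = more expression) plus Gaussian noise; housekeeping
#' Cts sit at stable means with small noise. One row per animal x gene.
#'
#' @param n_per_cell animals per Sex x Diet cell.
#' @param targets character vector of target gene names.
#' @param hk_genes exactly two housekeeping gene names.
#' @param region brain region label attached to all rows.
#' @param ct_effects named list: for each target, a named numeric vector of
#'   cycle shifts among `c(sex_M=, diet_LPD=, interaction_M_LPD=)`.
#' @param base_ct base cycle for targets.
#' @param sd residual sd for target Cts (cycles).
#' @param hk_sd sd for housekeeping Cts.
#' @param seed integer seed.
#' @return a `ct_table` data.frame (`animal_id`, `sex`, `diet`, `region`,
#'   `gene`, `ct`) with `hk_genes` attribute.
#' @export
simulate_ct <- function(n_per_cell = 10L, targets = c("Npy", "Npy1r"),
                        hk_genes = c("Gapdh", "Actb"), region = "amygdala",
                        ct_effects = list(), base_ct = 25, sd = 0.3,
                        hk_sd = 0.05, seed = 1L) {
  stopifnot(length(hk_genes) == 2, n_per_cell >= 1)
  cells <- expand.grid(sex = c("F", "M"), diet = c("CTRL", "LPD"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  animals <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  animals$animal_id <- sprintf("q%03d", seq_len(nrow(animals)))
  hk_means <- stats::setNames(c(18, 19), hk_genes)
  with_seed(seed, {
    rows <- list()
    for (g in targets) {
      shifts <- ct_effects[[g]] %||% numeric(0)
      mu <- rep(base_ct, nrow(animals))
      if (!is.na(s <- shifts["sex_M"]) && length(s)) mu <- mu + s * (animals$sex == "M")
      if (!is.na(s <- shifts["diet_LPD"]) && length(s)) mu <- mu + s * (animals$diet == "LPD")
      if (!is.na(s <- shifts["interaction_M_LPD"]) && length(s))
        mu <- mu + s * (animals$sex == "M" & animals$diet == "LPD")
      rows[[g]] <- data.frame(animal_id = animals$animal_id, sex = animals$sex,
                              diet = animals$diet, region = region, gene = g,
                              ct = mu + stats::rnorm(nrow(animals), sd = sd))
    }
    for (h in hk_genes) {
      rows[[h]] <- data.frame(animal_id = animals$animal_id, sex = animals$sex,
                              diet = animals$diet, region = region, gene = h,
                              ct = hk_means[[h]] + stats::rnorm(nrow(animals), sd = hk_sd))
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    structure(tab, class = c("ct_table", "data.frame"), hk_genes = hk_genes)
  })
}

#' Simulate per-animal behavioral measures for a factorial design
#'
#' Gaussian responses with declared cell means over a Sex x Diet layout, e.g.
#' a pure crossover interaction for power checks of the factorial GLM engine.
#'
#' @param cell_means named numeric vector with names `F.CTRL`, `M.CTRL`,
#'   `F.LPD`, `M.LPD` (any subset order), or a single number for all cells.
#' @param sd common residual sd.
#' @param n_per_cell animals per cell.
#' @param seed integer seed.
#' @return data.frame with `animal_id`, `sex`, `diet`, `value`.
#' @export
simulate_behavior <- function(cell_means = 0, sd = 1, n_per_cell = 15L, seed = 1L) {
  cells <- expand.grid(sex = c("F", "M"), diet = c("CTRL", "LPD"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(cells$sex, cells$diet, sep = ".")
  mu <- if (length(cell_means) == 1) stats::setNames(rep(cell_means, 4), key)
        else cell_means[key]
  stopifnot(!anyNA(mu))
  animals <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  animals$animal_id <- sprintf("b%03d", seq_len(nrow(animals)))
  with_seed(seed, {
    animals$value <- mu[paste(animals$sex, animals$diet, sep = ".")] +
      stats::rnorm(nrow(animals), sd = sd)
    rownames(animals) <- NULL
    animals[, c("animal_id", "sex", "diet", "value")]
  })
}
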