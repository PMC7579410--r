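#' Cohort design for the synthetic timecourse generator
#'
#' Captures the study geometry and the variance components of the simulated
#' log2 LFQ model. Defaults emulate a six-fish, ten-timepoint immunization
#' study in which individual differences dominate the proteome and roughly
#' 15% of proteins respond to sampling day in one of five archetypal
#' temporal shapes.
#'
#' The per-observation model on the log2 scale is
#' `y[p,f,d] = baseline_p + fish_pf + effect_size * g_p(d) * responder_p + eps`,
#' with `baseline_p ~ N(mu0, 1)`, residual `eps ~ N(0, sigma_noise^2)` and a
#' per-(protein, fish) intercept
#' `fish_pf = sigma_individual * (sqrt(w) F_f + sqrt(1-w) G_pf)` whose
#' component `F_f` is shared across proteins (sample-level individual
#' signature, weight `w = fish_effect_cor`) and `G_pf` protein-specific.
#' Archetype profiles `g` are zero-mean and unit-SD across days, so
#' `effect_size` is the day-to-day SD of a planted effect in log2 units
#' (peak excursion roughly 1.4-2x that).
#'
#' @param n_individuals number of fish.
#' @param days integer sampling days post-immunization.
#' @param n_proteins number of retained proteins.
#' @param responder_fraction fraction of proteins carrying a day effect.
#' @param sigma_individual SD (log2) of the per-(protein, fish) intercept.
#' @param sigma_noise residual SD (log2).
#' @param effect_size day-profile SD (log2) of a planted effect.
#' @param fish_effect_cor fraction of individual variance shared across
#'   proteins (0 = fully protein-specific, 1 = one offset per fish).
#' @param missing_rate target overall missing fraction after masking.
#' @param mnar_strength logistic slope of missingness on the abundance
#'   z-score (0 = missing completely at random).
#' @param baseline_mean mean log2 abundance.
#' @param seed integer master seed; all randomness derives from it.
#' @return object of class `cohort_design` (a named list).
#' @export
cohort_design <- function(n_individuals = 6L,
                          days = c(0L, 7L, 14L, 21L, 28L, 35L, 42L, 56L, 70L, 84L),
                          n_proteins = 278L,
                          responder_fraction = 0.15,
                          sigma_individual = 0.75,
                          sigma_noise = 0.5,
                          effect_size = 1.0,
                          fish_effect_cor = 0.5,
                          missing_rate = 0.0078,
                          mnar_strength = 1.0,
                          baseline_mean = 25,
                          seed = 1L) {
  stopifnot(n_individuals >= 2L, length(days) >= 2L, n_proteins >= 1L,
            responder_fraction >= 0, responder_fraction <= 1,
            sigma_individual >= 0, sigma_noise >= 0, effect_size >= 0,
            fish_effect_cor >= 0, fish_effect_cor <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (anyDuplicated(days)) stop("duplicate days")
  structure(list(n_individuals = as.integer(n_individuals),
                 days = as.integer(days),
                 n_proteins = as.integer(n_proteins),
                 responder_fraction = responder_fraction,
                 sigma_individual = sigma_individual,
                 sigma_noise = sigma_noise,
                 effect_size = effect_size,
                 fish_effect_cor = fish_effect_cor,
                 missing_rate = missing_rate,
                 mnar_strength = mnar_strength,
                 baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Archetypal temporal response profiles
#'
#' Five piecewise-linear mean shapes over the sampling days, mirroring the
#' qualitative cluster archetypes of immunization timecourses: `A1` a late
#' single peak, `A2` a slow monotone rise, `B1` an early spike followed by a
#' plateau, `B2` a mid-course peak with a late trough, `B3` early-high
#' decaying. Each profile is interpolated to the requested days, then
#' centred to mean 0 and scaled to unit SD across days, so every archetype
#' is planted with the same day-to-day variance for a given effect size.
#'
#' @param days integer sampling days (the default ten-day design spans
#'   day 0 to day 84).
#' @return matrix with one row per archetype (`A1`, `A2`, `B1`, `B2`, `B3`),
#'   one column per day.
#' @export
archetype_profiles <- function(days = c(0L, 7L, 14L, 21L, 28L, 35L, 42L, 56L, 70L, 84L)) {
  if (length(days) < 2L) stop("need at least two days")
  knots <- list(
    A1 = cbind(c(0, 42, 56, 70, 84), c(0, 0, 0.4, 1, 0.6)),
    A2 = cbind(c(0, 84), c(0, 1)),
    B1 = cbind(c(0, 7, 14, 84), c(0, 1, 0.75, 0.75)),
    B2 = cbind(c(0, 14, 28, 56, 84), c(0, 0.7, 1, -0.4, 0.1)),
    B3 = cbind(c(0, 21, 42, 84), c(1, 0.35, 0, 0))
  )
  prof <- t(vapply(knots, function(k) {
    stats::approx(k[, 1L], k[, 2L], xout = pmin(pmax(days, 0), 84),
                  rule = 2)$y
  }, numeric(length(days))))
  prof <- prof - rowMeans(prof)
  prof <- prof / apply(prof, 1L, stats::sd)
  colnames(prof) <- days
  prof
}

# Counter-based substreams: every simulated unit draws from its own seed
# derived from (master seed, stream index), so enlarging a simulation never
# perturbs units already generated.
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in c(index + 1, 104729)) {
    s <- (s * 48271 + k) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one paralog pair at a target percent identity
#'
#' Creates a duplicate of `template` carrying uniformly placed substitutions
#' (each drawn from the 19 alternative residues) so that the realized
#' identity is the nearest achievable to `target_identity` (exact when the
#' grid allows; always within half a grid step). The two records carry
#' distinct gene ids and reciprocal ohnolog metadata in their chromosome
#' field, emulating duplicates retained from a whole-genome duplication.
#'
#' @param template amino-acid string (canonical residues), length >= 50.
#' @param target_identity percent, in `[50, 100]`.
#' @param seed integer seed.
#' @param accession_prefix prefix for the two accessions.
#' @return a two-row [protein_records()] data.frame.
#' @export
simulate_paralog_pair <- function(template, target_identity, seed,
                                  accession_prefix = "SIM") {
  template <- toupper(template)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", template)) {
    stop("non-canonical residue in template")
  }
  L <- nchar(template)
  if (L < 50L) stop("template shorter than 50 residues")
  if (target_identity < 50 || target_identity > 100) {
    stop("target_identity must be in [50, 100]")
  }
  n_sub <- round(L * (100 - target_identity) / 100)
  aa <- strsplit(template, "")[[1L]]
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  dup <- with_seed(seed, {
    pos <- if (n_sub > 0L) sample.int(L, n_sub) else integer()
    for (i in pos) {
      aa[i] <- sample(setdiff(alphabet, aa[i]), 1L)
    }
    paste(aa, collapse = "")
  })
  acc <- paste0(accession_prefix, "_", c("a", "b"))
  protein_records(acc, c(template, dup),
                  gene_id = paste0(accession_prefix, c("_gene_a", "_gene_b")),
                  chromosome = paste0("ohnolog:", rev(acc)))
}

#' Simulate a proteome of random families with paralog pairs
#'
#' Random sequences (uniform residues, lengths uniform in 100-600) for
#' `n_families` gene families; a fraction of families is expanded into a
#' paralog pair at a percent identity drawn uniformly from
#' `identity_range`, emulating duplicate retention after a whole-genome
#' duplication. Deterministic given `seed`; each family has its own
#' substream, so increasing `n_families` leaves earlier families unchanged.
#'
#' @param n_families number of gene families.
#' @param duplicate_fraction fraction of families with a retained duplicate.
#' @param identity_range length-2 numeric, percent identity bounds.
#' @param seed integer seed.
#' @return a [protein_records()] data.frame; paralog pairs share an
#'   accession prefix and carry ohnolog metadata.
#' @export
simulate_proteome <- function(n_families, duplicate_fraction = 0.5,
                              identity_range = c(75, 99), seed = 1L) {
  if (n_families <= 0L) stop("n_families must be positive")
  stopifnot(duplicate_fraction >= 0, duplicate_fraction <= 1,
            length(identity_range) == 2L)
  n_dup <- round(n_families * duplicate_fraction)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  recs <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    fam_seed <- substream_seed(seed, i)
    template <- with_seed(fam_seed, {
      L <- sample(100:600, 1L)
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    })
    fam_id <- sprintf("FAM%04d", i)
    if (i <= n_dup) {
      ident <- with_seed(substream_seed(seed, -i),
                         stats::runif(1, identity_range[1L], identity_range[2L]))
      recs[[i]] <- simulate_paralog_pair(template, ident,
                                         seed = substream_seed(fam_seed, 1L),
                                         accession_prefix = fam_id)
    } else {
      recs[[i]] <- protein_records(paste0(fam_id, "_a"), template,
                                   gene_id = paste0(fam_id, "_gene_a"))
    }
  }
  do.call(rbind, recs)
}

#' Simulate a log2 abundance tensor and its ground truth
#'
#' Draws the per-observation model described in [cohort_design()]: protein
#' baselines, per-(protein, fish) individual intercepts with a shared
#' sample-level component, archetypal day effects for a planted responder
#' subset, and i.i.d. residual noise. The returned tensor is on the log2
#' scale and fully observed; apply [apply_missingness()] for non-detections.
#' The shared fish component is standardized across individuals so the
#' planted between-individual variance is exact by construction.
#'
#' Responder count is `round(responder_fraction * n_proteins)`; responders
#' are the first proteins in each archetype's round-robin assignment, and
#' the truth table records the archetype and planted per-day mean profile.
#'
#' @param design a [cohort_design()].
#' @param proteins optional accession vector (length `n_proteins`); default
#'   `P0001...`.
#' @return list with elements `tensor` (an [abundance_tensor()], log2 scale)
#'   and `truth` (data.frame: `protein`, `is_responder`, `archetype`, and
#'   one `profile_d<day>` column per day).
#' @export
simulate_abundance <- function(design, proteins = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  np <- design$n_proteins
  if (is.null(proteins)) proteins <- sprintf("P%04d", seq_len(np))
  if (length(proteins) != np) stop("length(proteins) != design$n_proteins")
  nf <- design$n_individuals
  nd <- length(design$days)
  fish <- sprintf("F%d", seq_len(nf))
  samples <- data.frame(individual = rep(fish, each = nd),
                        day = rep(design$days, nf),
                        stringsAsFactors = FALSE)

  prof <- archetype_profiles(design$days)
  # a zero effect size plants no responders: truth must match the data
  n_resp <- if (design$effect_size > 0) {
    round(design$responder_fraction * np)
  } else 0L
  archetype <- rep(NA_integer_, np)
  if (n_resp > 0L) archetype[seq_len(n_resp)] <- rep_len(seq_len(nrow(prof)), n_resp)
  is_responder <- !is.na(archetype)

  # shared per-fish signature, standardized across the cohort
  F_f <- with_seed(substream_seed(design$seed, 0L), stats::rnorm(nf))
  if (nf > 1L && stats::sd(F_f) > 0) F_f <- (F_f - mean(F_f)) / stats::sd(F_f)
  w <- design$fish_effect_cor

  values <- matrix(NA_real_, np, nf * nd)
  day_idx <- rep(seq_len(nd), nf)
  fish_idx <- rep(seq_len(nf), each = nd)
  for (p in seq_len(np)) {
    sp <- substream_seed(design$seed, p)
    row <- with_seed(sp, {
      baseline <- stats::rnorm(1, design$baseline_mean, 1)
      G_pf <- stats::rnorm(nf)
      fish_eff <- design$sigma_individual *
        (sqrt(w) * F_f + sqrt(1 - w) * G_pf)
      eff <- if (is_responder[p]) design$effect_size * prof[archetype[p], ] else
        numeric(nd)
      baseline + fish_eff[fish_idx] + eff[day_idx] +
        stats::rnorm(nf * nd, 0, design$sigma_noise)
    })
    values[p, ] <- row
  }

  profile <- matrix(0, np, nd,
                    dimnames = list(proteins, paste0("profile_d", design$days)))
  if (n_resp > 0L) {
    profile[seq_len(n_resp), ] <-
      design$effect_size * prof[archetype[seq_len(n_resp)], , drop = FALSE]
  }
  truth <- data.frame(protein = proteins, is_responder = is_responder,
                      archetype = ifelse(is_responder,
                                         rownames(prof)[archetype], NA_character_),
                      profile, stringsAsFactors = FALSE, row.names = NULL)
  list(tensor = abundance_tensor(values, proteins, samples, scale = "log2"),
       truth = truth)
}

#' Mask entries with low-abundance-biased (MNAR) missingness
#'
#' Each observed entry is masked with probability
#' `plogis(a - mnar_strength * z)`, where `z` is the entry's z-score within
#' the tensor and the intercept `a` is calibrated so the overall expected
#' masked fraction equals `missing_rate`. `mnar_strength = 0` recovers
#' missingness completely at random; positive values bias non-detection
#' toward low abundances, as for LFQ intensities near the detection limit.
#' Already-missing entries stay missing.
#'
#' @param tensor an [abundance_tensor()].
#' @param missing_rate target overall masked fraction, in `[0, 1)`.
#' @param mnar_strength logistic slope on the abundance z-score.
#' @param seed integer seed.
#' @return the tensor with an updated mask.
#' @export
apply_missingness <- function(tensor, missing_rate, mnar_strength = 1.0,
                              seed = 1L) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  if (missing_rate < 0) stop("missing_rate must be >= 0")
  if (missing_rate == 0) return(tensor)
  obs <- which(tensor$mask)
  v <- tensor$values[obs]
  z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, length(v))
  # overall masked fraction counts already-missing entries toward the target
  target_new <- missing_rate * length(tensor$mask) - sum(!tensor$mask)
  if (target_new <= 0) return(tensor)
  target_p <- target_new / length(obs)
  f <- function(a) mean(stats::plogis(a - mnar_strength * z)) - target_p
  a <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  p_mask <- stats::plogis(a - mnar_strength * z)
  drop <- with_seed(substream_seed(seed, 7L),
                    stats::runif(length(obs)) < p_mask)
  mask <- tensor$mask
  mask[obs[drop]] <- FALSE
  abundance_tensor(tensor$values, tensor$proteins, tensor$samples,
                   mask = mask, scale = tensor$scale)
}

#' Simulate antigen-specific antibody titre curves
#'
#' Each fish follows a logistic rise on the log2 scale with a per-fish
#' random onset (uniform in `onset_range`, midpoint onset + 14 d, slope 7 d)
#' and a per-fish amplitude uniform in `amplitude_range` (defaults
#' log2(3)-log2(5), the 3-5-fold rises typical of a primary response).
#' The noiseless latent curve is returned alongside the noisy titre so that
#' designated immunoglobulin proteins in an abundance tensor can be driven
#' by the same latent response (see [add_titre_coupling()]).
#'
#' @param design a [cohort_design()] (uses its individuals, days, seed).
#' @param amplitude_range length-2 numeric, log2 amplitude bounds.
#' @param onset_range length-2 numeric, onset day bounds.
#' @param noise_sd SD of additive measurement noise on the titre.
#' @param seed integer seed (defaults to the design seed).
#' @return data.frame with columns `individual`, `day`, `latent`, `titre`.
#' @export
simulate_titres <- function(design, amplitude_range = log2(c(3, 5)),
                            onset_range = c(21, 42), noise_sd = 0.1,
                            seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  nf <- design$n_individuals
  fish <- sprintf("F%d", seq_len(nf))
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    pars <- with_seed(substream_seed(seed, 1000L + f), {
      c(onset = stats::runif(1, onset_range[1L], onset_range[2L]),
        amp = stats::runif(1, amplitude_range[1L], amplitude_range[2L]))
    })
    latent <- pars[["amp"]] *
      stats::plogis((design$days - (pars[["onset"]] + 14)) / 7)
    noise <- with_seed(substream_seed(seed, 2000L + f),
                       stats::rnorm(length(design$days), 0, noise_sd))
    out[[f]] <- data.frame(individual = fish[f], day = design$days,
                           latent = latent, titre = latent + noise,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Drive designated proteins with a latent titre response
#'
#' Adds `coupling` times each fish's latent titre curve to the named
#' proteins of a log2 tensor, so that (at `coupling = 1`) the simulated
#' immunoglobulin proteins and the antibody titre share one underlying
#' response, as when plasma IgM quantified by LC-MS tracks the
#' ELISA-measured titre.
#'
#' @param tensor log2-scale [abundance_tensor()].
#' @param titres data.frame from [simulate_titres()].
#' @param accessions proteins to drive.
#' @param coupling coupling strength in `[0, 1]`.
#' @return the modified tensor.
#' @export
add_titre_coupling <- function(tensor, titres, accessions, coupling = 1) {
  stopifnot(inherits(tensor, "abundance_tensor"),
            coupling >= 0, coupling <= 1)
  missing <- setdiff(accessions, tensor$proteins)
  if (length(missing)) stop("unknown protein: ", missing[1L])
  if (tensor$scale != "log2") stop("tensor must be on the log2 scale")
  key <- paste0(tensor$samples$individual, "_d", tensor$samples$day)
  tkey <- paste0(titres$individual, "_d", titres$day)
  idx <- match(key, tkey)
  if (anyNA(idx)) stop("titre table does not cover sample ", key[is.na(idx)][1L])
  add <- coupling * titres$latent[idx]
  values <- tensor$values
  rows <- match(accessions, tensor$proteins)
  values[rows, ] <- sweep(values[rows, , drop = FALSE], 2L, add, `+`)
  abundance_tensor(values, tensor$proteins, tensor$samples,
                   mask = tensor$mask, scale = "log2")
}
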