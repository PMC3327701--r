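# Synthetic cohort generator: emulates the group structure the analysis
# assumes (group-specific ICV distributions, volume-ICV proportionality,
# lateralized graded atrophy) so the pipeline is testable without scans.

#' Specify one subject group of a synthetic cohort
#'
#' @param name group label: one of \code{control}, \code{TLE-HA_L},
#'   \code{TLE-HA_R}, \code{TLE-N_L}, \code{TLE-N_R}
#' @param n subject count (>= 2)
#' @param icv_mean,icv_sd intracranial volume distribution, cm^3
#' @param effects named numeric: fractional volume reduction in [0, 1) per
#'   affected structure (canonical names); structures absent are unaffected
#' @param age_mean,age_sd age distribution, years (truncated to [18, 70])
#' @param sex_ratio fraction female
#' @return a \code{GroupSpec} (classed list)
#' @export
groupSpec <- function(name, n, icv_mean, icv_sd, effects = numeric(),
                      age_mean = 35, age_sd = 10, sex_ratio = 0.5) {
  if (n < 2) stop("group '", name, "': n must be >= 2")
  if (icv_sd <= 0) stop("icv_sd must be > 0")
  if (length(effects)) {
    bad <- setdiff(names(effects), structureNames())
    if (length(bad))
      stop("unknown structure name(s) in effects: ", paste(bad, collapse = ", "))
    if (any(effects < 0 | effects >= 1))
      stop("effects must lie in [0, 1)")
  }
  structure(list(name = name, n = as.integer(n), icv_mean = icv_mean,
                 icv_sd = icv_sd, effects = effects, age_mean = age_mean,
                 age_sd = age_sd, sex_ratio = sex_ratio),
            class = "GroupSpec")
}

#' Configure a synthetic cohort
#'
#' The generative model is volume proportional to ICV with lognormal
#' multiplicative noise: for structure s of a subject with intracranial
#' volume ICV (converted to mm^3),
#' \deqn{v_s = f_s \cdot ICV \cdot (1 - e_s) \cdot \exp(\epsilon),\quad
#'   \epsilon \sim N(0, \sigma^2)}
#' where \eqn{f_s} is the base ICV fraction, \eqn{e_s} the group's atrophy
#' effect and \eqn{\sigma} is set so the multiplicative coefficient of
#' variation equals \code{noise_cv} (\eqn{\sigma^2 = \log(1 + cv^2)}).
#'
#' @param groups list of \code{\link{groupSpec}}
#' @param base_fractions named numeric covering all 83 structures: volume as
#'   a fraction of ICV; defaults to the catalog's typical volumes over a
#'   1483 cm^3 reference ICV
#' @param noise_cv multiplicative noise coefficient of variation (default
#'   0.08, a typical regional-volume CV)
#' @param seed integer RNG seed
#' @return a \code{CohortConfig} (classed list)
#' @export
cohortConfig <- function(groups, base_fractions = defaultBaseFractions(),
                         noise_cv = 0.08, seed = 1L) {
  stopifnot(length(groups) >= 1, all(vapply(groups, inherits, TRUE, "GroupSpec")))
  miss <- setdiff(structureNames(), names(base_fractions))
  if (length(miss))
    stop("base_fractions must cover all 83 structures; missing: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (any(base_fractions[structureNames()] <= 0))
    stop("base_fractions must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(groups = groups,
                 base_fractions = base_fractions[structureNames()],
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Default per-structure ICV fractions
#'
#' Typical adult regional volumes from the catalog divided by the reference
#' control ICV of 1483 cm^3. Synthetic reference values, not measurements.
#' @return named numeric(83)
#' @export
defaultBaseFractions <- function() {
  cat83 <- structureCatalog()
  stats::setNames(cat83$typical_volume_mm3 / (1483 * 1000), cat83$name)
}

#' Default graded atrophy effects
#'
#' Ipsilaterally-defined fractional volume reductions. For the hippocampal
#' atrophy (TLE-HA) phenotype: hippocampus 0.30, then eight further
#' structures graded 0.15 down to 0.05. For the MRI-negative (TLE-N)
#' phenotype: ten orbitofronto-temporal and nigral structures graded 0.10
#' down to 0.03. Defined for a left-sided focus; use \code{\link{sideSwap}}
#' on the names for right-sided groups.
#'
#' @param phenotype "TLE-HA" or "TLE-N"
#' @param side "L" or "R"
#' @return named numeric of fractional reductions
#' @export
defaultEffects <- function(phenotype = c("TLE-HA", "TLE-N"), side = c("L", "R")) {
  phenotype <- match.arg(phenotype)
  side <- match.arg(side)
  if (phenotype == "TLE-HA") {
    nm <- c("Hippocampus_L", "Amygdala_L", "AntOrbitalG_L", "AntTempLobeLat_L",
            "FusiformG_L", "Thalamus_L", "Cerebellum_L", "ParahippocampalG_L",
            "MedOrbitalG_L")
    ef <- c(0.30, round(seq(0.15, 0.05, length.out = 8), 4))
  } else {
    nm <- c("SubstantiaNigra_L", "AntOrbitalG_L", "StraightG_L",
            "MedOrbitalG_L", "SubgenualFrC_L", "LingualG_L",
            "AntTempLobeLat_L", "SubcallosalA_L", "Amygdala_L", "Cerebellum_L")
    ef <- round(seq(0.10, 0.03, length.out = 10), 4)
  }
  if (side == "R") nm <- sideSwap(nm)
  stats::setNames(ef, nm)
}

#' Default study-sized cohort configuration
#'
#' Five groups at the study's sizes and ICV distributions: 28 controls
#' (ICV 1483 +/- 160 cm^3), 60 TLE-HA split 33 left / 27 right
#' (1387 +/- 128), 20 TLE-N split 11 left / 9 right (1423 +/- 150), with
#' the default graded atrophy effects planted ipsilaterally.
#'
#' @param seed integer RNG seed
#' @param noise_cv multiplicative noise CV (default 0.08)
#' @return a \code{CohortConfig}
#' @export
defaultCohortConfig <- function(seed = 1L, noise_cv = 0.08) {
  cohortConfig(list(
    groupSpec("control", 28, 1483, 160, age_mean = 32, age_sd = 11,
              sex_ratio = 14 / 28),
    groupSpec("TLE-HA_L", 33, 1387, 128, defaultEffects("TLE-HA", "L"),
              age_mean = 39, age_sd = 12, sex_ratio = 29 / 60),
    groupSpec("TLE-HA_R", 27, 1387, 128, defaultEffects("TLE-HA", "R"),
              age_mean = 39, age_sd = 12, sex_ratio = 29 / 60),
    groupSpec("TLE-N_L", 11, 1423, 150, defaultEffects("TLE-N", "L"),
              age_mean = 36, age_sd = 10, sex_ratio = 9 / 20),
    groupSpec("TLE-N_R", 9, 1423, 150, defaultEffects("TLE-N", "R"),
              age_mean = 36, age_sd = 10, sex_ratio = 9 / 20)),
    noise_cv = noise_cv, seed = seed)
}

.group_side <- function(name) {
  if (grepl("_L$", name)) "L" else if (grepl("_R$", name)) "R" else "none"
}

#' Generate a synthetic cohort
#'
#' Draws, per subject, ICV ~ Normal(icv_mean, icv_sd) truncated at > 0, then
#' per structure the proportional-to-ICV lognormal-noise volume (see
#' \code{\link{cohortConfig}}). Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohortConfig}}
#' @return an unnormalized \linkS4class{TleCohort} (volumes in mm^3) with
#'   group, side, age and sex columns
#' @examples
#' coh <- generateCohort(defaultCohortConfig(seed = 7))
#' table(subjectData(coh)$group)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  snames <- structureNames()
  bf <- config$base_fractions
  sigma <- sqrt(log(1 + config$noise_cv^2))
  withr::with_seed(config$seed, {
    parts <- lapply(config$groups, function(g) {
      icv <- stats::rnorm(g$n, g$icv_mean, g$icv_sd)
      while (any(icv <= 0))  # truncation at > 0 by redraw
        icv[icv <= 0] <- stats::rnorm(sum(icv <= 0), g$icv_mean, g$icv_sd)
      red <- rep(1, length(snames))
      names(red) <- snames
      if (length(g$effects)) red[names(g$effects)] <- 1 - g$effects
      eps <- if (sigma > 0)
        matrix(stats::rnorm(83L * g$n, 0, sigma), 83L, g$n) else
        matrix(0, 83L, g$n)
      vol <- (bf * red) %o% (icv * 1000) * exp(eps)  # mm^3
      age <- round(pmin(70, pmax(18, stats::rnorm(g$n, g$age_mean, g$age_sd))))
      sex <- ifelse(stats::runif(g$n) < g$sex_ratio, "F", "M")
      list(vol = vol,
           cd = data.frame(group = g$name, side = .group_side(g$name),
                           age = age, sex = sex, icv_cm3 = icv,
                           stringsAsFactors = FALSE))
    })
    vol <- do.call(cbind, lapply(parts, `[[`, "vol"))
    cd <- do.call(rbind, lapply(parts, `[[`, "cd"))
    ids <- sprintf("S%03d_%s", seq_len(nrow(cd)), gsub("[^A-Za-z]", "", cd$group))
    colnames(vol) <- ids
    rownames(vol) <- snames
    rownames(cd) <- ids
    TleCohort(vol, cd, normalized = FALSE)
  })
}

#' Generate a pair of toy label volumes
#'
#' The first volume partitions the grid into \code{n_regions} slabs along
#' the first axis; the second is a copy in which a fraction of voxels is
#' reassigned to a random \emph{other} label (with a single region the sole
#' label maps to itself). A fixture for fusion and overlap experiments.
#'
#' @param shape integer(3) grid size
#' @param n_regions number of regions (>= 1)
#' @param flip_fraction proportion of voxels to reassign, in [0, 1]
#' @param seed integer RNG seed
#' @param region_names optional character(n_regions) naming the labels
#' @return list of two \linkS4class{LabelVolume}s: \code{original},
#'   \code{degraded}
#' @export
generateLabelPair <- function(shape, n_regions, flip_fraction, seed = 1L,
                              region_names = paste0("Region", seq_len(n_regions))) {
  stopifnot(length(shape) == 3L, n_regions >= 1,
            flip_fraction >= 0, flip_fraction <= 1,
            length(region_names) == n_regions)
  if (shape[1] < n_regions)
    stop("grid too small: first axis (", shape[1], ") cannot host ",
         n_regions, " slab regions")
  slab <- if (n_regions == 1L) rep(1L, shape[1]) else
    as.integer(cut(seq_len(shape[1]), n_regions, labels = FALSE))
  grid <- array(rep(slab, times = shape[2] * shape[3]), dim = shape)
  codes <- stats::setNames(region_names, as.character(seq_len(n_regions)))
  orig <- LabelVolume(grid, voxelDims = c(1, 1, 1), codes = codes)
  degraded <- withr::with_seed(seed, {
    g <- grid
    nflip <- round(flip_fraction * length(g))
    if (nflip > 0) {
      idx <- sample.int(length(g), nflip)
      if (n_regions == 1L) {
        g[idx] <- 1L  # sole non-background label maps to itself
      } else {
        cur <- g[idx]
        r <- sample.int(n_regions - 1L, nflip, replace = TRUE)
        g[idx] <- r + (r >= cur)  # uniform over the other labels
      }
    }
    LabelVolume(g, voxelDims = c(1, 1, 1), codes = codes)
  })
  list(original = orig, degraded = degraded)
}
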