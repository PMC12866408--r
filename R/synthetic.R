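## Synthetic-data generator: every input the pipeline consumes, with known
## ground truth. The whole-blood bolus is a delayed tri-exponential
## (Feng-type) model: for s = t - tau > 0,
##   C_wb(t) = (A1 s - A2 - A3) e^(-l1 s) + A2 e^(-l2 s) + A3 e^(-l3 s)
## which rises linearly from 0 at the bolus arrival and washes out through
## two slower exponentials.

#' Parameters of the synthetic whole-blood bolus model
#'
#' @param tau bolus arrival delay (min).
#' @param A1 slope of the initial rise (kBq/mL/min).
#' @param A2,A3 washout amplitudes (kBq/mL).
#' @param lambda1,lambda2,lambda3 decay rates (per min), strictly
#'   decreasing.
#' @return object of class \code{InputModelParams}.
#' @examples
#' p <- inputModelParams()
#' predict(p, c(0, 0.5, 2, 60))
#' @export
inputModelParams <- function(tau = 0.25, A1 = 600, A2 = 60, A3 = 30,
                             lambda1 = 4, lambda2 = 0.25, lambda3 = 0.015) {
  if (!(lambda1 > lambda2 && lambda2 > lambda3))
    stop("decay rates must satisfy lambda1 > lambda2 > lambda3")
  if (any(c(lambda3, A1, A2, A3) < 0) || tau < 0)
    stop("rates, amplitudes and delay must be nonnegative")
  m <- structure(list(tau = tau, A1 = A1, A2 = A2, A3 = A3,
                      lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
                 class = "InputModelParams")
  tt <- seq(0, 120, by = 0.05)
  if (any(predict(m, tt) < 0))
    stop("model predicts negative whole-blood activity on [0, 120] min")
  m
}

#' @export
predict.InputModelParams <- function(object, t, ...) {
  s <- t - object$tau
  v <- ifelse(s <= 0, 0,
    (object$A1 * s - object$A2 - object$A3) * exp(-object$lambda1 * s) +
      object$A2 * exp(-object$lambda2 * s) +
      object$A3 * exp(-object$lambda3 * s))
  pmax(v, 0)
}

#' @export
print.InputModelParams <- function(x, ...) {
  cat(sprintf(
    "InputModelParams: tau=%.3g min, A=(%.3g/min, %.3g, %.3g), lambda=(%.3g, %.3g, %.3g)/min\n",
    x$tau, x$A1, x$A2, x$A3, x$lambda1, x$lambda2, x$lambda3))
  invisible(x)
}

#' Simulate a whole-blood plus metabolite-corrected plasma input
#'
#' Evaluates the bolus model on a uniform grid and applies the multiplicative
#' plasma correction C_p(t) = C_wb(t) (r0 + r1 t) f(t).
#'
#' @param params an \code{InputModelParams} (default [inputModelParams()]).
#' @param p2wb a \code{PlasmaToBloodModel} (default [defaultPlasmaToBlood()]).
#' @param pf a \code{ParentFractionModel} (default [defaultParentFraction()]).
#' @param tEnd end of the grid (min), default 120.
#' @param gridStep grid step (min), default 0.05.
#' @return an \linkS4class{InputFunction}.
#' @export
simulateInput <- function(params = inputModelParams(),
                          p2wb = defaultPlasmaToBlood(),
                          pf = defaultParentFraction(),
                          tEnd = 120, gridStep = 0.05) {
  stopifnot(gridStep > 0, tEnd > 0)
  grid <- seq(0, tEnd, by = gridStep)
  wb <- predict(params, grid)
  ratio <- predict(p2wb, grid)
  frac <- predict(pf, grid)
  if (any(ratio <= 0)) stop("invalid model: plasma-to-blood ratio <= 0 on grid")
  if (any(frac < -1e-9 | frac > 1 + 1e-9))
    stop("invalid model: parent fraction outside [0, 1] on grid")
  inputFunction(grid, wb, wb * ratio * pmin(pmax(frac, 0), 1))
}

#' Frame-noise specification for simulated TACs
#'
#' Zero-mean Gaussian noise with per-frame standard deviation
#' scale * sqrt(C_model / duration): the count-statistics heuristic under
#' which short, low-count frames are noisiest. \code{scale = 0} is
#' noise-free.
#'
#' @param scale unitless noise scale (>= 0).
#' @param seed integer RNG seed.
#' @return object of class \code{NoiseSpec}.
#' @export
noiseSpec <- function(scale = 0, seed = 1) {
  stopifnot(scale >= 0)
  structure(list(scale = scale, seed = as.integer(seed)), class = "NoiseSpec")
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Simulate a frame-averaged regional TAC
#'
#' Forward-models the two-tissue prediction over the schedule (the same
#' forward model the fitter uses) and adds zero-mean Gaussian frame noise per
#' the \code{NoiseSpec}. Identical seeds give identical output.
#'
#' @param params a \linkS4class{TwoTcmParams}.
#' @param input an \linkS4class{InputFunction} covering the schedule.
#' @param fs a \linkS4class{FrameSchedule} (default [defaultFrameSchedule()]).
#' @param noise a \code{NoiseSpec} (default noise-free).
#' @param region region name for the output column.
#' @return a single-region \linkS4class{TacTable}.
#' @export
simulateTac <- function(params, input, fs = defaultFrameSchedule(),
                        noise = noiseSpec(), region = "region1") {
  mu <- twotcmPredict(params, input, fs)
  if (noise$scale > 0) {
    sdv <- noise$scale * sqrt(pmax(mu, 0) / frameDurations(fs))
    mu <- mu + withSeed(noise$seed, rnorm(length(mu), 0, sdv))
  }
  tacTable(fs, setNames(list(mu), region))
}

#' Specification of a synthetic test-retest cohort
#'
#' Each animal's underlying level is its genotype mean plus a normal
#' between-animal effect (SD \code{sdBetween}); each session adds independent
#' normal within-animal noise (SD \code{sdWithin}). The generative ICC is
#' sdBetween^2 / (sdBetween^2 + sdWithin^2).
#'
#' @param nPerGenotype animals per genotype (>= 2).
#' @param means named numeric vector of genotype means, e.g.
#'   \code{c(WT = 3, HET = 6)}.
#' @param sdBetween between-animal SD (>= 0).
#' @param sdWithin within-animal (session) SD (>= 0).
#' @param seed integer RNG seed.
#' @return object of class \code{TrtCohortSpec}.
#' @export
trtCohortSpec <- function(nPerGenotype = 8, means = c(WT = 3, HET = 6),
                          sdBetween = 0.5, sdWithin = 0.3, seed = 1) {
  stopifnot(nPerGenotype >= 2, sdBetween >= 0, sdWithin >= 0,
            !is.null(names(means)), all(nzchar(names(means))))
  structure(list(nPerGenotype = as.integer(nPerGenotype), means = means,
                 sdBetween = sdBetween, sdWithin = sdWithin,
                 seed = as.integer(seed)),
            class = "TrtCohortSpec")
}

#' Generative ICC implied by a cohort specification
#' @param spec a \code{TrtCohortSpec}.
#' @return sdBetween^2 / (sdBetween^2 + sdWithin^2).
#' @export
expectedIcc <- function(spec) {
  spec$sdBetween^2 / (spec$sdBetween^2 + spec$sdWithin^2)
}

#' Simulate a long-format test-retest cohort
#'
#' value(animal, session) = genotype mean + animal effect + session noise,
#' two sessions (test, retest) per animal. Reproducible under the seed
#' carried by \code{spec}.
#'
#' @param spec a \code{TrtCohortSpec}.
#' @param region region label attached to the records.
#' @param metric metric label attached to the records.
#' @return data.frame: animal, genotype, session, region, metric, value.
#' @export
simulateTrtCohort <- function(spec, region = "striatum", metric = "V_T") {
  genos <- names(spec$means)
  n <- spec$nPerGenotype
  withSeed(spec$seed, {
    rows <- list()
    for (g in genos) {
      animalEff <- rnorm(n, 0, spec$sdBetween)
      for (i in seq_len(n)) {
        id <- sprintf("%s_%02d", g, i)
        base <- spec$means[[g]] + animalEff[i]
        for (ses in c("test", "retest")) {
          rows[[length(rows) + 1L]] <- data.frame(
            animal = id, genotype = g, session = ses, region = region,
            metric = metric, value = base + rnorm(1, 0, spec$sdWithin))
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Default two-tissue parameters by genotype
#'
#' The genotype effect enters through the binding-associated rate k3 with
#' delivery and efflux shared: WT k3 = 0.015, HET k3 = 0.06 (min^-1) on
#' K1 = 0.3, k2 = 0.15, k4 = 0.03, vB = 0.03, giving true V_T of 3 (WT) and
#' 6 (HET) mL/cm^3.
#'
#' @param genotype "WT" or "HET".
#' @return a \linkS4class{TwoTcmParams}.
#' @export
genotypeParams <- function(genotype = c("WT", "HET")) {
  genotype <- match.arg(genotype)
  k3 <- if (genotype == "HET") 0.06 else 0.015
  twotcmParams(K1 = 0.3, k2 = 0.15, k3 = k3, k4 = 0.03, vB = 0.03)
}

#' Write a complete synthetic two-genotype, two-session study to disk
#'
#' Emits, in the package's tab-separated dialects: one TAC table per
#' animal/session (five brain regions with genotype-dependent striatal and
#' subcortical binding), one pooled blood table sampled at 5/15/30/60/90 min,
#' and one subject table (dose ~ 4.1 MBq, weight ~ 30 g). Per-animal kinetic
#' variability is induced by jittering K1 (between-animal) and per-session
#' noise on the frames.
#'
#' @param dir output directory (created if needed).
#' @param nPerGenotype animals per genotype.
#' @param noiseScale frame-noise scale passed to [noiseSpec()].
#' @param sdK1 between-animal SD of the K1 jitter (fraction of K1).
#' @param seed integer RNG seed.
#' @param gridStep input-function grid step (min).
#' @return invisibly, a list with the file paths written
#'   (\code{tac_files}, \code{blood_file}, \code{subject_file},
#'   \code{idif_file}).
#' @export
writeSyntheticStudy <- function(dir, nPerGenotype = 8, noiseScale = 0.05,
                                sdK1 = 0.08, seed = 1, gridStep = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- defaultFrameSchedule()
  input <- simulateInput(gridStep = gridStep)
  pf <- defaultParentFraction(); p2 <- defaultPlasmaToBlood()

  ## pooled blood table at the standard sampling times
  bt <- data.frame(time = c(5, 15, 30, 60, 90))
  wbm <- inputModelParams()
  bt$whole_blood <- predict(wbm, bt$time)
  bt$plasma <- bt$whole_blood * predict(p2, bt$time)
  bt$parent_fraction <- predict(pf, bt$time)
  bloodFile <- file.path(dir, "blood.tsv")
  writeBloodTable(bt, bloodFile)

  ## whole-blood IDIF, frame-averaged like any other extracted curve
  idifFile <- file.path(dir, "idif.tsv")
  wbFrames <- frameAverage(gridTimes(input), wholeBlood(input), fs)
  writeTacTable(tacTable(fs, list(whole_blood = wbFrames)), idifFile)

  regions <- c("striatum", "motor_cortex", "hippocampus", "thalamus",
               "cerebellum")
  ## region-specific binding: cerebellum lowest, thalamus highest in HET
  k3mult <- c(striatum = 1, motor_cortex = 0.8, hippocampus = 0.9,
              thalamus = 1.2, cerebellum = 0.6)

  subj <- list(); tacFiles <- character(0)
  withSeed(seed, {
    for (g in c("WT", "HET")) {
      base <- genotypeParams(g)
      for (i in seq_len(nPerGenotype)) {
        id <- sprintf("%s_%02d", g, i)
        K1i <- base@K1 * exp(rnorm(1, 0, sdK1))
        dose <- round(rnorm(1, 4.1, 0.3), 3)
        wt <- round(rnorm(1, 30, 2), 1)
        mass <- round(runif(1, 0.2, 1.0), 3)  # microgram/kg, capped design
        for (ses in c("test", "retest")) {
          vals <- lapply(regions, function(rg) {
            p <- twotcmParams(K1i, base@k2, base@k3 * k3mult[[rg]],
                              base@k4, base@vB)
            tacValues(simulateTac(p, input, fs,
                                  noiseSpec(noiseScale,
                                            sample.int(1e8, 1))), 1)
          })
          names(vals) <- regions
          f <- file.path(dir, sprintf("tac_%s_%s.tsv", id, ses))
          writeTacTable(tacTable(fs, vals), f)
          tacFiles <- c(tacFiles, f)
          subj[[length(subj) + 1L]] <- data.frame(
            subject = id, genotype = g, session = ses,
            dose_mbq = dose, weight_g = wt, mass_ug_per_kg = mass)
        }
      }
    }
  })
  subjFile <- file.path(dir, "subjects.tsv")
  writeSubjectTable(do.call(rbind, subj), subjFile)
  invisible(list(tac_files = tacFiles, blood_file = bloodFile,
                 subject_file = subjFile, idif_file = idifFile))
}
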