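## End-to-end study runner: input-function fitting -> per-subject kinetic
## quantification -> test-retest battery -> group statistics, with
## tab-separated reports and a run log. Identical config + seed gives
## byte-identical numeric outputs.

#' Study configuration for the pipeline runner
#'
#' Expects the study-directory layout written by [writeSyntheticStudy()]:
#' \code{blood.tsv}, \code{subjects.tsv}, \code{idif.tsv} (whole-blood IDIF
#' as a single-region TAC table), and one \code{tac_<subject>_<session>.tsv}
#' per scan.
#'
#' @param studyDir directory with the input tables.
#' @param outDir directory for the reports (default
#'   \code{file.path(studyDir, "reports")}).
#' @param suvWindow SUV window in minutes.
#' @param tStar Logan t* in minutes (or "auto").
#' @param restarts,seed multi-start settings for [fit2tcm()].
#' @param weights fit weights (see [fit2tcm()]).
#' @param gridStep input-function grid step (min).
#' @param extraRandomTerms passed to [iccReml()].
#' @return a \code{StudyConfig} list.
#' @export
studyConfig <- function(studyDir, outDir = file.path(studyDir, "reports"),
                        suvWindow = c(100, 120), tStar = 30, restarts = 10,
                        seed = 1, weights = "duration", gridStep = 0.05,
                        extraRandomTerms = FALSE) {
  cfg <- structure(list(
    studyDir = studyDir, outDir = outDir,
    bloodFile = file.path(studyDir, "blood.tsv"),
    subjectFile = file.path(studyDir, "subjects.tsv"),
    idifFile = file.path(studyDir, "idif.tsv"),
    suvWindow = suvWindow, tStar = tStar, restarts = restarts,
    seed = as.integer(seed), weights = weights, gridStep = gridStep,
    extraRandomTerms = extraRandomTerms), class = "StudyConfig")
  for (f in c(cfg$bloodFile, cfg$subjectFile, cfg$idifFile))
    if (!file.exists(f)) stop("config error: missing input file ", f)
  cfg
}

writeReport <- function(df, path) {
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full quantification and reliability pipeline
#'
#' Stages: (1) fit the pooled parent-fraction and plasma-to-whole-blood
#' models from the blood table and metabolite-correct the whole-blood IDIF;
#' (2) per subject/session/region, fit the 2TCM, run Logan and compute SUV;
#' (3) if both sessions are present, run the test-retest battery (rTRV,
#' aTRV, Bland-Altman, ICC); (4) genotype group statistics (Welch, Cohen's
#' d, sample-size planning). Per-scan failures are recorded and the pipeline
#' continues.
#'
#' @param config a \code{StudyConfig}.
#' @return invisibly, a list with the report data.frames (\code{kinetics},
#'   \code{trt}, \code{group}, \code{power}), the fitted input models, the
#'   failure log, and the report file paths.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  blood <- readBloodTable(config$bloodFile)
  subjects <- readSubjectTable(config$subjectFile)
  pf <- fitParentFraction(blood)
  p2 <- fitPlasmaToBlood(blood)
  idif <- readTacTable(config$idifFile)
  mids <- frameMidpoints(schedule(idif))
  input <- correctIdif(mids, tacValues(idif, 1), p2, pf,
                       gridStep = config$gridStep,
                       tEnd = scanDuration(schedule(idif)))

  failures <- character(0)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    tf <- file.path(config$studyDir,
                    sprintf("tac_%s_%s.tsv", s$subject, s$session))
    res <- try({
      tac <- readTacTable(tf)
      q <- quantifyRegions(tac, input, dose = s$dose_mbq,
                           weight = s$weight_g, tStar = config$tStar,
                           suvWindow = config$suvWindow,
                           weights = config$weights,
                           restarts = config$restarts, seed = config$seed)
      cbind(data.frame(subject = s$subject, genotype = s$genotype,
                       session = s$session), q)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, sprintf("%s/%s: %s", s$subject, s$session,
                                      conditionMessage(attr(res, "condition"))))
    } else rows[[length(rows) + 1L]] <- res
  }
  kin <- do.call(rbind, rows)
  paths <- c(kinetics = writeReport(kin, file.path(config$outDir,
                                                   "kinetics_report.tsv")))

  ## test-retest battery when both sessions are present
  trt <- NULL
  if (!is.null(kin) && all(c("test", "retest") %in% kin$session)) {
    long <- rbind(
      data.frame(animal = kin$subject, genotype = kin$genotype,
                 session = kin$session, region = kin$region,
                 metric = "V_T", value = kin$V_T_logan),
      data.frame(animal = kin$subject, genotype = kin$genotype,
                 session = kin$session, region = kin$region,
                 metric = "SUV", value = kin$suv))
    trt <- tryCatch(trtReport(long, extraRandomTerms = config$extraRandomTerms),
                    error = function(e) {
                      failures <<- c(failures,
                                     paste("test-retest battery:",
                                           conditionMessage(e)))
                      NULL
                    })
    if (!is.null(trt))
      paths <- c(paths, trt = writeReport(trt, file.path(config$outDir,
                                                         "trt_report.tsv")))
  }

  ## group statistics on the test session (needs >= 2 animals per genotype)
  grp <- NULL; pow <- NULL
  kt <- kin[kin$session == "test", ]
  enough <- !is.null(kt) && nrow(kt) &&
    length(unique(kt$genotype)) == 2 &&
    all(table(unique(kt[, c("subject", "genotype")])$genotype) >= 2)
  if (enough) {
    grp <- welchByRegion(data.frame(region = kt$region,
                                    genotype = kt$genotype,
                                    value = kt$V_T_logan))
    pow <- powerTable(sort(unique(abs(grp$d))))
    paths <- c(paths,
               group = writeReport(grp, file.path(config$outDir,
                                                  "group_report.tsv")),
               power = writeReport(pow, file.path(config$outDir,
                                                  "power_report.tsv")))
  }

  log <- c(sprintf("petkin %s", as.character(utils::packageVersion("petkin"))),
           sprintf("seed: %d", config$seed),
           sprintf("t*: %s min; SUV window: %g-%g min", config$tStar,
                   config$suvWindow[1], config$suvWindow[2]),
           sprintf("restarts: %d; weights: %s; grid step: %g min",
                   config$restarts, config$weights, config$gridStep),
           sprintf("parent fraction: a1=%.6g mu1=%.6g a2=%.6g mu2=%.6g",
                   pf$a1, pf$mu1, pf$a2, pf$mu2),
           sprintf("plasma-to-blood: r0=%.6g r1=%.6g", p2$r0, p2$r1),
           sprintf("scans quantified: %d; failures: %d",
                   length(rows), length(failures)),
           if (length(failures)) paste("FAILED", failures))
  writeLines(log, file.path(config$outDir, "run_log.txt"))

  invisible(list(kinetics = kin, trt = trt, group = grp, power = pow,
                 parentFraction = pf, plasmaToBlood = p2, input = input,
                 failures = failures, paths = paths))
}
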