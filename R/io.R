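## Tab-separated file dialects. One fixed unit system: times in minutes,
## activities kBq/mL, doses MBq, weights g, injected mass microgram/kg.
## Readers validate and reject; they never silently coerce.

numericColumn <- function(raw, col, path) {
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) & !is.na(raw) & nzchar(raw))
  if (length(bad))
    stop(sprintf("parse error in %s: non-numeric value '%s' at row %d, column '%s'",
                 basename(path), raw[bad[1]], bad[1], col))
  x
}

readTsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  df
}

#' Read / write a regional TAC table
#'
#' Tab-separated dialect: header \code{frame_start_min}, \code{frame_end_min},
#' then one column per region; decimal points, no thousands separators.
#' Schedule invariants (start at 0, contiguity, positive durations) are
#' validated on read and a schema error names the offending row.
#'
#' @param path file path.
#' @param tac a \linkS4class{TacTable} (for writing).
#' @return \code{readTacTable} returns a \linkS4class{TacTable};
#'   \code{writeTacTable} returns \code{path} invisibly.
#' @export
readTacTable <- function(path) {
  df <- readTsv(path, c("frame_start_min", "frame_end_min"))
  starts <- numericColumn(df$frame_start_min, "frame_start_min", path)
  ends <- numericColumn(df$frame_end_min, "frame_end_min", path)
  if (nrow(df) < 1) stop(basename(path), ": empty TAC table")
  if (abs(starts[1]) > 1e-9)
    stop(sprintf("schema error in %s: first frame starts at %g, not 0 (row 1)",
                 basename(path), starts[1]))
  durs <- ends - starts
  if (any(durs <= 0)) {
    r <- which(durs <= 0)[1]
    stop(sprintf("schema error in %s: nonpositive frame duration at row %d",
                 basename(path), r))
  }
  if (nrow(df) > 1) {
    gap <- abs(starts[-1] - ends[-length(ends)])
    if (any(gap > 1e-9)) {
      r <- which(gap > 1e-9)[1] + 1L
      stop(sprintf("schema error in %s: frame at row %d does not start where row %d ends",
                   basename(path), r, r - 1L))
    }
  }
  regions <- setdiff(names(df), c("frame_start_min", "frame_end_min"))
  if (!length(regions)) stop(basename(path), ": no region columns")
  vals <- vapply(regions, function(cn) numericColumn(df[[cn]], cn, path),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(NULL, regions))
  tacTable(frameSchedule(starts, durs), vals)
}

#' @rdname readTacTable
#' @export
writeTacTable <- function(tac, path) {
  fs <- schedule(tac)
  df <- data.frame(frame_start_min = frameStarts(fs),
                   frame_end_min = frameEnds(fs), check.names = FALSE)
  df <- cbind(df, as.data.frame(tac@values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a blood-sampling table
#'
#' Tab-separated dialect: \code{time}, \code{whole_blood}, \code{plasma},
#' optional \code{parent_fraction}. Validated per the blood-table invariants
#' (strictly increasing times, nonnegative activities, fractions in [0, 1]).
#'
#' @param path file path.
#' @param samples a blood-table data.frame (for writing).
#' @return \code{readBloodTable} returns the validated data.frame.
#' @export
readBloodTable <- function(path) {
  df <- readTsv(path, c("time", "whole_blood", "plasma"))
  out <- data.frame(time = numericColumn(df$time, "time", path),
                    whole_blood = numericColumn(df$whole_blood, "whole_blood", path),
                    plasma = numericColumn(df$plasma, "plasma", path))
  if ("parent_fraction" %in% names(df))
    out$parent_fraction <- numericColumn(df$parent_fraction,
                                         "parent_fraction", path)
  validateBloodTable(out)
}

#' @rdname readBloodTable
#' @export
writeBloodTable <- function(samples, path) {
  validateBloodTable(samples)
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a subject table
#'
#' Tab-separated dialect: \code{subject}, \code{genotype} (WT or HET),
#' \code{session}, \code{dose_mbq}, \code{weight_g}, optional
#' \code{mass_ug_per_kg}. (subject, session) pairs must be unique; doses and
#' weights positive.
#'
#' @param path file path.
#' @param subjects a subject-table data.frame (for writing).
#' @return \code{readSubjectTable} returns the validated data.frame.
#' @export
readSubjectTable <- function(path) {
  df <- readTsv(path, c("subject", "genotype", "session", "dose_mbq",
                        "weight_g"))
  out <- data.frame(subject = df$subject, genotype = df$genotype,
                    session = df$session,
                    dose_mbq = numericColumn(df$dose_mbq, "dose_mbq", path),
                    weight_g = numericColumn(df$weight_g, "weight_g", path))
  if ("mass_ug_per_kg" %in% names(df))
    out$mass_ug_per_kg <- numericColumn(df$mass_ug_per_kg, "mass_ug_per_kg",
                                        path)
  validateSubjectTable(out)
}

#' @rdname readSubjectTable
#' @export
writeSubjectTable <- function(subjects, path) {
  validateSubjectTable(subjects)
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readSubjectTable
#' @param x a subject-table data.frame.
#' @export
validateSubjectTable <- function(x) {
  if (!all(x$genotype %in% c("WT", "HET")))
    stop("validation error: genotype must be WT or HET")
  if (any(x$dose_mbq <= 0)) stop("validation error: dose must be > 0")
  if (any(x$weight_g <= 0)) stop("validation error: body weight must be > 0")
  key <- paste(x$subject, x$session)
  if (anyDuplicated(key))
    stop("uniqueness error: duplicate (subject, session): ",
         key[duplicated(key)][1])
  x
}
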