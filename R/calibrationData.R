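#' Construct a calibration dataset
#'
#' @param dose numeric vector of doses (Gy).
#' @param counts matrix (or list of numeric vectors, one per dose) of cell
#'   frequencies: entry `[i, k+1]` is the number of cells with `k`
#'   aberrations at `dose[i]`. Rows of unequal length are zero-padded.
#' @return a [CalibrationData-class] object.
#' @examples
#' cd <- CalibrationData(c(0.5, 1), list(c(980, 20), c(940, 58, 2)))
#' doses(cd)
#' @export
CalibrationData <- function(dose, counts) {
  if (is.list(counts)) {
    K <- max(lengths(counts))
    counts <- t(vapply(counts, function(r) c(r, numeric(K - length(r))),
                       numeric(K)))
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  colnames(counts) <- paste0("c", seq_len(ncol(counts)) - 1L)
  rownames(counts) <- NULL
  new("CalibrationData", dose = as.numeric(dose), counts = counts)
}

#' @describeIn CalibrationData the dose vector.
#' @param object a `CalibrationData`.
#' @export
setMethod("doses", "CalibrationData", function(object) object@dose)

#' @describeIn CalibrationData the cell-frequency matrix.
#' @export
setMethod("cellCounts", "CalibrationData", function(object) object@counts)

#' @describeIn CalibrationData subset by dose row.
#' @param x a `CalibrationData`.
#' @param i row (dose) index.
#' @export
setMethod("[", "CalibrationData", function(x, i) {
  CalibrationData(x@dose[i], x@counts[i, , drop = FALSE])
})

#' Drop one dose row (e.g. to hold it out as a test sample)
#'
#' @param data a [CalibrationData-class].
#' @param dose the dose value to remove.
#' @return the reduced `CalibrationData`.
#' @export
dropDose <- function(data, dose) {
  i <- which(abs(data@dose - dose) < 1e-9)
  if (length(i) != 1L) stop("dose ", dose, " not found in the dataset")
  data[-i]
}

#' @export
as.data.frame.CalibrationData <- function(x, ...) {
  data.frame(dose = x@dose, x@counts)
}

setMethod("show", "CalibrationData", function(object) {
  cat(sprintf("CalibrationData: %d doses, %d cells, counts 0..%d\n",
              length(object@dose), sum(object@counts),
              ncol(object@counts) - 1L))
  df <- as.data.frame(object)
  df$ybar <- round(rowSums(sweep(object@counts, 2,
                                 seq_len(ncol(object@counts)) - 1, "*")) /
                   rowSums(object@counts), 4)
  print(df, row.names = FALSE)
  invisible(object)
})

#' Read / write calibration data as CSV
#'
#' The CSV dialect has a `dose` column followed by columns `c0, c1, ...`
#' holding the number of cells with 0, 1, ... aberrations.
#'
#' @param file path to a CSV file.
#' @return `readCalibration` returns a [CalibrationData-class];
#'   `writeCalibration` writes one and returns `file` invisibly.
#' @export
readCalibration <- function(file) {
  df <- read.csv(file)
  if (!"dose" %in% names(df)) stop("CSV needs a 'dose' column")
  CalibrationData(df$dose, as.matrix(df[grep("^c[0-9]+$", names(df))]))
}

#' @rdname readCalibration
#' @param data a [CalibrationData-class].
#' @export
writeCalibration <- function(data, file) {
  write.csv(as.data.frame(data), file, row.names = FALSE)
  invisible(file)
}

#' Bundled example calibration datasets
#'
#' Two published whole-table calibration experiments, shipped as plain CSV:
#' `"dicentrics"` - dicentric counts after acute cobalt-60 gamma exposure at
#' six doses (semi-automated scoring, Metafer system), equidispersed;
#' `"micronuclei"` - micronucleus counts in binucleated cells after
#' protracted gamma exposure at eleven doses (~5000 cells each), strongly
#' overdispersed. Both include the row conventionally held out as a known
#' test sample (1.5 Gy and 0.1 Gy respectively).
#'
#' @param name which dataset.
#' @return a [CalibrationData-class].
#' @examples
#' cd <- exampleCalibration("dicentrics")
#' uTest(cellCounts(cd)[4, ])
#' @export
exampleCalibration <- function(name = c("dicentrics", "micronuclei")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".csv"), package = "doseCalib",
                   mustWork = TRUE)
  readCalibration(f)
}

#' Construct a test (patient) sample
#'
#' @param freq frequency vector: element `k+1` = number of cells with `k`
#'   aberrations.
#' @param trueDose optional simulated ground-truth dose (Gy).
#' @return a [TestSample-class].
#' @examples
#' ts <- TestSample(c(487, 13))
#' @export
TestSample <- function(freq, trueDose = NA_real_) {
  new("TestSample", freq = as.numeric(freq),
      trueDose = as.numeric(trueDose))
}

#' @describeIn TestSample number of scored cells `m`.
#' @param object a `TestSample`.
#' @export
setMethod("cellCounts", "TestSample", function(object) sum(object@freq))

#' Total number of aberrations `s` in a test sample
#' @param x a [TestSample-class].
#' @export
totalAberrations <- function(x) {
  sum((seq_along(x@freq) - 1) * x@freq)
}

setMethod("show", "TestSample", function(object) {
  cat(sprintf("TestSample: m = %d cells, s = %d aberrations\n",
              cellCounts(object), totalAberrations(object)))
  if (!is.na(object@trueDose))
    cat("  simulated at true dose", object@trueDose, "Gy\n")
  invisible(object)
})
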