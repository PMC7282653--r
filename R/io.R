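#' Read and write trial summary tables
#'
#' A summary table holds one non-inferiority analysis per row with the
#' fixed columns `study_id`, `mu_ni_hat`, `sigma_ni`, `mu_h_hat`,
#' `sigma_h`, `delta0`, `alpha`; extra columns are carried through
#' untouched. CSV files are comma-separated with a header and period
#' decimals; JSON files hold an array of row objects. Values survive a
#' write/read round trip at full double precision.
#'
#' @param path file path.
#' @param data a summary table (any data frame with the fixed columns).
#' @param format `"csv"` or `"json"`; inferred from the file extension
#'   when `NULL`.
#'
#' @return `read_summary_table()` returns a validated tibble;
#'   `write_summary_table()` returns `path` invisibly.
#'
#' @examples
#' path <- system.file("extdata", "xeloda.csv", package = "fracret")
#' read_summary_table(path)
#' @export
read_summary_table <- function(path, format = NULL) {
  format <- resolve_format(path, format)
  if (!file.exists(path)) stop_data(sprintf("File not found: %s", path))
  d <- if (format == "csv") {
    tryCatch(
      readr::read_csv(path, show_col_types = FALSE,
                      progress = FALSE, col_types = readr::cols()),
      error = function(e) stop_data(sprintf("Cannot parse %s: %s", path,
                                            conditionMessage(e))))
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  validate_summary_records(d, path)
}

#' @rdname read_summary_table
#' @export
write_summary_table <- function(data, path, format = NULL) {
  format <- resolve_format(path, format)
  d <- validate_summary_records(as_tibble(data), "`data`")
  if (format == "csv") {
    readr::write_csv(d, path)
  } else {
    jsonlite::write_json(d, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("csv", "json")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}

record_columns <- c("study_id", "mu_ni_hat", "sigma_ni", "mu_h_hat",
                    "sigma_h", "delta0", "alpha")

validate_summary_records <- function(d, what) {
  if (nrow(d) == 0L) stop_data(sprintf("%s contains no records.", what))
  missing_cols <- setdiff(record_columns, names(d))
  if (length(missing_cols) > 0L) {
    stop_data(sprintf("%s is missing column(s): %s.", what,
                      paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(record_columns, "study_id")) {
    x <- d[[col]]
    if (is.character(x)) x <- suppressWarnings(as.numeric(x))
    if (!is.numeric(x) || any(!is.finite(x))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(d[[col]]))))[1]
      stop_data(sprintf("%s: column `%s`, row %d is not a finite number.",
                        what, col, bad))
    }
    d[[col]] <- x
  }
  for (col in c("sigma_ni", "sigma_h")) {
    if (any(d[[col]] <= 0)) {
      stop_data(sprintf("%s: column `%s`, row %d must be positive.",
                        what, col, which(d[[col]] <= 0)[1]))
    }
  }
  d$study_id <- as.character(d$study_id)
  d
}

#' Read raw two-arm observations
#'
#' Reads a CSV file with two numeric columns, `historical` (control vs
#' placebo effects from the historical trials) and `ni` (treatment vs
#' control effects from the NI trial), and returns them in the long
#' `(arm, value)` form that [gpv_test()] consumes. Each arm needs at least
#' two finite values; missing entries are an error naming the offending
#' row.
#'
#' @param path CSV file path.
#' @return a tibble with columns `arm` and `value`.
#' @export
read_raw_samples <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("File not found: %s", path))
  d <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols()),
    error = function(e) stop_data(sprintf("Cannot parse %s: %s", path,
                                          conditionMessage(e))))
  for (col in c("historical", "ni")) {
    if (!col %in% names(d)) {
      stop_data(sprintf("%s is missing column `%s`.", path, col))
    }
    x <- suppressWarnings(as.numeric(d[[col]]))
    if (any(!is.finite(x))) {
      stop_data(sprintf("%s: column `%s`, row %d is missing or not numeric.",
                        path, col, which(!is.finite(x))[1]))
    }
    if (length(x) < 2L) {
      stop_data(sprintf("%s: column `%s` needs at least two values.",
                        path, col))
    }
    d[[col]] <- x
  }
  tibble(arm = rep(c("historical", "ni"), c(nrow(d), nrow(d))),
         value = c(d$historical, d$ni))
}

#' The Xeloda non-inferiority trial summaries
#'
#' Summary statistics of the Xeloda (capecitabine) metastatic colorectal
#' cancer programme: two randomized trials (S014695, S014796) and their
#' pooled intent-to-treat analysis comparing Xeloda with 5-FU/LV, each
#' paired with one of two random-effects meta-analyses of the historical
#' 5-FU/LV-vs-5-FU effect — 10 control trials (effect 0.2341, SE 0.0750)
#' or 8 control trials (0.2398, SE 0.0593). `mu_ni_hat` is the log hazard
#' ratio of Xeloda vs 5-FU/LV with standard error `sigma_ni`. The
#' regulatory question was whether Xeloda retains at least 50% of the
#' 5-FU/LV effect, hence `delta0 = 0.5` at one-sided `alpha = 0.025`.
#'
#' @return a 6-row summary tibble (see [read_summary_table()] for the
#'   column contract) with the extra column `historical_trials`.
#' @examples
#' xeloda_summary() |> ni_test()
#' @export
xeloda_summary <- function() {
  tibble(
    study_id = rep(c("S014695", "S014796", "Pooled"), 2),
    historical_trials = rep(c(10L, 8L), each = 3),
    mu_ni_hat = rep(c(-0.0036, -0.0844, -0.0432), 2),
    sigma_ni = rep(c(0.0868, 0.0867, 0.0613), 2),
    mu_h_hat = rep(c(0.2341, 0.2398), each = 3),
    sigma_h = rep(c(0.0750, 0.0593), each = 3),
    delta0 = 0.5,
    alpha = 0.025)
}

#' Write packaged or synthetic fixture files
#'
#' `name = "xeloda"` writes the six [xeloda_summary()] rows as a summary
#' CSV. `name = "synthetic"` writes a raw two-arm CSV of normal draws for
#' the GPV test, with parameters taken from `params`:
#' `mu_h`, `mu_ni` (arm means), `sigma_h`, `sigma_ni` (per-observation
#' SDs), and `n` (per-arm size); defaults 0.24, 0.12, 0.12, 0.12, 30.
#'
#' @param name `"xeloda"` or `"synthetic"`.
#' @param path output file path.
#' @param params named list overriding synthetic-arm parameters.
#' @param seed integer seed for the synthetic draws.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(name, path, params = list(), seed = 1L) {
  name <- tryCatch(match.arg(name, c("xeloda", "synthetic")),
                   error = function(e) {
                     stop_domain("`name` must be \"xeloda\" or \"synthetic\".")
                   })
  if (name == "xeloda") {
    write_summary_table(xeloda_summary(), path, format = "csv")
    return(invisible(path))
  }
  p <- utils::modifyList(
    list(mu_h = 0.24, mu_ni = 0.12, sigma_h = 0.12, sigma_ni = 0.12, n = 30),
    params)
  seed_stream(seed, 1L)
  d <- tibble(historical = rnorm(p$n, p$mu_h, p$sigma_h),
              ni = rnorm(p$n, p$mu_ni, p$sigma_ni))
  readr::write_csv(d, path)
  invisible(path)
}
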