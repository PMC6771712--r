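#' Read individual-level survival data from delimited text
#'
#' Reads a delimited file (comma default, tab accepted) with a header row,
#' maps the named columns onto the `time` / `status` / `cause` layout, and
#' keeps every remaining column as a covariate.  Rows with missing values in
#' the modeled covariates are dropped with a message reporting the count
#' (the count is also stored as attribute `"n_dropped"`).
#'
#' @param path file path.
#' @param mapping named list giving the input column names for `time`,
#'   `status` and `cause` (defaults: same names).
#' @param covariates covariate columns to keep and require complete
#'   (default: all remaining columns).
#' @param sep field separator ("," or "\t").
#' @return validated survival data.frame.
#' @export
read_surv_data <- function(path, mapping = list(), covariates = NULL,
                           sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (std in c("time", "status", "cause")) {
    src <- mapping[[std]] %||% std
    if (!src %in% names(df)) stop("input lacks column '", src, "' for ", std)
    names(df)[names(df) == src] <- std
  }
  if (is.null(covariates))
    covariates <- setdiff(names(df), c("time", "status", "cause"))
  keep <- stats::complete.cases(df[covariates])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " row(s) with missing covariate values")
  out <- as_surv_data(df[keep, , drop = FALSE], covariates)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a life table from delimited text
#'
#' Expects columns `sex`, `age`, `year`, `rate`; `sex` may be coded 0/1 or
#' as strings starting with "m"/"f" (case-insensitive).
#'
#' @param path file path.
#' @param sep field separator.
#' @return a [life_table()].
#' @export
read_life_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (is.character(df$sex)) {
    s <- tolower(substr(df$sex, 1, 1))
    if (!all(s %in% c("m", "f"))) stop("sex strings must start with m/f")
    df$sex <- ifelse(s == "f", 1L, 0L)
  }
  life_table(df)
}

#' Compose first-event competing-risks records from an MGUS-style table
#'
#' Input rows carry two outcome pairs per subject: time to progression to
#' plasma cell malignancy (PCM) with its indicator, and time to last
#' follow-up / death with the death indicator.  Treating progression as an
#' absorbing state, each subject contributes a single competing-risks
#' record: cause 1 (PCM) at the progression time if progression occurred
#' (even when death follows later); otherwise cause 2 (death) at the
#' follow-up time if the subject died; otherwise censored at last
#' follow-up.  Times are converted from months to years by default.  Rows
#' with missing modeled covariates are dropped with a reported count.
#'
#' @param x data.frame, or path to a delimited file.
#' @param covariates covariate columns to keep complete (default
#'   `c("age", "sex", "mspike")`).
#' @param columns named list mapping `ptime`, `pstat`, `futime`, `death`
#'   onto the input columns (defaults: those names, as in the survival
#'   package's `mgus2`).
#' @param time_unit "months" (divide by 12) or "years".
#' @param sep separator when `x` is a path.
#' @return survival data.frame (`cause` 1 = PCM, 2 = death) with attribute
#'   `"n_dropped"`; a `sex` column given as "F"/"M" strings is recoded to
#'   1/0.
#' @export
load_mgus_like <- function(x, covariates = c("age", "sex", "mspike"),
                           columns = list(), time_unit = "months",
                           sep = ",") {
  if (is.character(x))
    x <- utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  cn <- function(k) columns[[k]] %||% k
  for (k in c("ptime", "pstat", "futime", "death"))
    if (!cn(k) %in% names(x)) stop("input lacks column '", cn(k), "'")
  ptime <- x[[cn("ptime")]]; pstat <- x[[cn("pstat")]]
  futime <- x[[cn("futime")]]; death <- x[[cn("death")]]
  if (any(ptime < 0 | futime < 0, na.rm = TRUE)) stop("negative times in input")
  if (any(pstat == 1 & ptime > futime, na.rm = TRUE))
    stop("progression recorded after last follow-up")
  scale <- switch(time_unit, months = 1 / 12, years = 1,
                  stop("time_unit must be 'months' or 'years'"))
  time <- ifelse(pstat == 1, ptime, futime) * scale
  cause <- ifelse(pstat == 1, 1L, ifelse(death == 1, 2L, 0L))
  out <- data.frame(time = time, status = as.integer(cause > 0), cause = cause)
  for (v in covariates) {
    if (!v %in% names(x)) stop("covariate not in input: ", v)
    col <- x[[v]]
    if (v == "sex" && (is.character(col) || is.factor(col)))
      col <- as.integer(toupper(substr(as.character(col), 1, 1)) == "F")
    out[[v]] <- col
  }
  keep <- stats::complete.cases(out[covariates]) & out$time > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " row(s) with missing covariates or non-positive time")
  out <- as_surv_data(out[keep, , drop = FALSE], covariates)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a prediction table to delimited text
#'
#' Writes numeric columns at full double precision (round trips are
#' lossless well beyond 12 significant digits).
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_cif_table <- function(x, path) {
  df <- as.data.frame(x)
  for (k in seq_along(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.17g", df[[k]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
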