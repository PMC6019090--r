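.SCHEMA <- c(tree_id = "tree_id", population_id = "population_id",
             zone = "zone", in_reserve = "in_reserve",
             dbh_t0_cm = "dbh_t0", dbh_t1_cm = "dbh_t1",
             debark_frac = "debark", prun_frac = "prun",
             wd_g_cm3 = "wd", lma_g_m2 = "lma")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a tree-record table
#'
#' Checks every row against the record invariants — DBH at first census
#' >= 2 cm, AGR > -1 (the log(AGR+1) response must exist), disturbance
#' fractions in \[0, 1\] (values in (1, 100\] trigger a
#' percent-to-fraction hint), positive traits — and aggregates all
#' violations into one error listing the offending rows.
#'
#' @param records Data frame with the internal record columns.
#' @return `records`, invisibly, when valid.
#' @export
validate_tree_records <- function(records) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(unname(.SCHEMA), c(names(records), "dbh_t1"))
  miss <- setdiff(miss, if ("agr" %in% names(records)) "dbh_t1")
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  probs <- character()
  note <- function(rows, msg) {
    if (length(rows))
      probs <<- c(probs, paste0(msg, " (row ",
                                paste(rows, collapse = ", "), ")"))
  }
  note(which(!is.finite(records$dbh_t0) | records$dbh_t0 < 2),
       "dbh_t0 below the 2 cm census threshold")
  note(which(!is.finite(records$agr) | records$agr <= -1),
       "agr <= -1, log(agr+1) undefined")
  for (f in c("debark", "prun")) {
    x <- records[[f]]
    note(which(is.finite(x) & x > 1 & x <= 100),
         paste0(f, " in (1, 100]: intensities are fractions in [0, 1], ",
                "divide percentages by 100"))
    note(which(!is.finite(x) | x < 0 | x > 100),
         paste0(f, " outside [0, 1]"))
  }
  note(which(!is.finite(records$wd) | records$wd <= 0), "wd must be > 0")
  note(which(!is.finite(records$lma) | records$lma <= 0), "lma must be > 0")
  if (length(probs))
    stop("invalid tree records:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  invisible(records)
}

#' Read and write the tree-record CSV
#'
#' The on-disk schema has exactly the header
#' `tree_id,population_id,zone,in_reserve,dbh_t0_cm,dbh_t1_cm,debark_frac,prun_frac,wd_g_cm3,lma_g_m2`
#' (UTF-8, `.` decimal separator). On read, `agr` is computed as
#' `dbh_t1 - dbh_t0` and every row is validated; all violations are
#' reported together with their row numbers. Lines starting with `#` are
#' treated as comments.
#'
#' @param path CSV path.
#' @return `read_tree_table`: a validated data frame with the internal
#'   column names (`dbh_t0`, `debark`, `wd`, ... plus `agr`).
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!identical(names(df), names(.SCHEMA)))
    stop("header mismatch: expected '", paste(names(.SCHEMA), collapse = ","),
         "' but found '", paste(names(df), collapse = ","), "'",
         call. = FALSE)
  names(df) <- unname(.SCHEMA)
  df$in_reserve <- as.logical(df$in_reserve)
  df$agr <- df$dbh_t1 - df$dbh_t0
  validate_tree_records(df)
  df
}

#' @rdname read_tree_table
#' @param records Data frame of tree records (internal column names).
#' @param meta Optional named character vector written as `# key=value`
#'   comment lines above the header.
#' @return `write_tree_table`: `path`, invisibly.
#' @export
write_tree_table <- function(records, path, meta = NULL) {
  stopifnot(is.data.frame(records))
  out <- records[, unname(.SCHEMA)]
  names(out) <- names(.SCHEMA)
  out$in_reserve <- tolower(as.character(out$in_reserve))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), "=", meta), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' A small djb2-style hash over the deparsed object, used to stamp output
#' files so reruns are auditable.
#'
#' @param x Any R object.
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
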