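#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x

## scalar-or-NA coercion for optional record fields
.opt_chr <- function(x) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) NA_character_ else as.character(x)[1]
}

.opt_num <- function(x) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) NA_real_ else as.numeric(x)[1]
}

## round half-up to `digits` decimals (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## RFC 4180 field quoting: quote when the field contains comma, quote or newline
.csv_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

## write a data.frame as RFC 4180 CSV with an unquoted header line
write_rfc4180 <- function(df, path) {
  header <- paste(names(df), collapse = ",")
  if (nrow(df) == 0) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  cols <- lapply(df, .csv_quote)
  rows <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

## is the character at position i of string s alphanumeric or hyphen?
## (hyphen counts as word-internal for entity matching)
.is_wordchar <- function(ch) grepl("[A-Za-z0-9-]", ch)

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
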