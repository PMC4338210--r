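## Annotated-TSV emitters and the plain-text key:value run configuration.

#' Write a data.frame as TSV with a metadata comment block
#'
#' Every output the package writes carries a `# metadata` header block of
#' `# key: value` lines (parameters, seed, package version) so the file is
#' reproducible from its own annotations. Numeric columns are formatted with
#' `formatC(..., format = "g", digits = 15)` for byte-stable re-runs.
#'
#' @param tab data.frame to write.
#' @param path output path.
#' @param metadata named character vector of extra annotation lines.
#' @return `path`, invisibly.
#' @export
writeAnnotatedTsv <- function(tab, path, metadata = character()) {
  meta <- c(package = paste0("haplodrift ",
                             as.character(utils::packageVersion("haplodrift"))),
            metadata)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# metadata", con)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  isNum <- vapply(tab, is.double, logical(1))
  tab[isNum] <- lapply(tab[isNum], formatC, format = "g", digits = 15)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text key:value run configuration
#'
#' One `key: value` pair per line; blank lines and `#` comments are ignored.
#' Unknown keys are rejected (typos must not silently fall back to
#' defaults). Values are returned as character; callers coerce.
#'
#' @param path config file path.
#' @param allowed character vector of permitted keys; `NULL` accepts any.
#' @return named character vector of settings.
#' @export
readRunConfig <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hit <- regexpr(":", lines, fixed = TRUE)
  if (any(hit < 0))
    stop("malformed config line (expected 'key: value'): ",
         lines[which(hit < 0)[1]], call. = FALSE)
  keys <- trimws(substr(lines, 1L, hit - 1L))
  vals <- trimws(substr(lines, hit + 1L, nchar(lines)))
  if (anyDuplicated(keys))
    stop("duplicate config key: ", keys[duplicated(keys)][1], call. = FALSE)
  if (!is.null(allowed)) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  setNames(vals, keys)
}
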