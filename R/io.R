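## JSONL / JSON serialization for corpora and ground truth.

#' Write a corpus to JSONL (one paper record per line)
#'
#' @param papers list of paper records
#' @param path output path
#' @return `path`, invisibly
#' @export
write_corpus <- function(papers, path) {
  lines <- vapply(papers, function(p) {
    p$affiliations <- lapply(p$affiliations, function(a)
      list(raw = a$raw, country = a$country))
    jsonlite::toJSON(p, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from JSONL
#'
#' @param path JSONL file, one paper record per line
#' @return list of paper records
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    p <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    p$doi <- if (is.null(p$doi)) NA_character_ else p$doi
    p$year <- as.integer(p$year)
    p$cited_guidelines <- as.character(unlist(p$cited_guidelines))
    p$affiliations <- lapply(p$affiliations, function(a)
      list(raw = if (is.null(a$raw)) NA_character_ else a$raw,
           country = if (is.null(a$country)) NA_character_ else a$country))
    p
  })
}

#' Write ground truth as JSON
#'
#' @param truth the `truth` element of a [generate_corpus()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  out <- list(universities = truth$universities,
              paper_orgs = truth$paper_orgs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(path)
}
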