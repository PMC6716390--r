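# CHAT-lite corpus dialect: UTF-8 text, one utterance per line,
# "SPEAKER<TAB>token token ...". Speaker codes starting with "ADU" (or "MOT",
# "FAT", "INV" for convenience) are treated as adult; "CHI" as child.

#' Read a CHAT-lite corpus file
#'
#' @param path Path to a UTF-8 text file, one utterance per line in the form
#'   `SPEAKER<TAB>token token ...`. Blank lines are skipped.
#' @return A `lexacq_corpus` tibble with columns `speaker` and `tokens`
#'   (list of character vectors). Tokenization is by whitespace; tokens are
#'   case-folded to lower case at matching time, not here.
#' @export
read_chat_lite <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(!nzchar(parts[, 2])))
    abort_config("malformed CHAT-lite line: expected 'SPEAKER<TAB>tokens'")
  tokens <- stringr::str_split(trimws(parts[, 2]), "\\s+")
  if (any(lengths(tokens) == 0))
    abort_config("utterances must contain at least one token")
  out <- tibble::tibble(speaker = parts[, 1], tokens = tokens)
  class(out) <- c("lexacq_corpus", class(out))
  out
}

#' Write a corpus in CHAT-lite format
#'
#' @param corpus A `lexacq_corpus` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chat_lite <- function(corpus, path) {
  lines <- paste0(corpus$speaker, "\t",
                  vapply(corpus$tokens, paste, "", collapse = " "))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Map a speaker code to a role.
speaker_role <- function(speaker) {
  ifelse(grepl("^(ADU|MOT|FAT|INV)", speaker), "adult",
         ifelse(grepl("^CHI", speaker), "child", "other"))
}

# Filter a corpus to a speaker role ("adult", "child", or "all").
filter_speaker <- function(corpus, speaker_filter) {
  if (identical(speaker_filter, "all")) return(corpus)
  corpus[speaker_role(corpus$speaker) == speaker_filter, , drop = FALSE]
}
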