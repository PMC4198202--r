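#' Canonical emotion classes
#'
#' The four emotion classes used throughout the package, in canonical order.
#' The order (anger, joy, sadness, disgust) is fixed and is used for
#' deterministic tie-breaking wherever an argmax over classes can tie.
#'
#' @format Character vector of length 4.
#' @export
EMOTIONS <- c("anger", "joy", "sadness", "disgust")

#' Validate an emotion name
#'
#' @param emotion Character scalar, one of [EMOTIONS].
#' @return The validated emotion name, invisibly useful in pipelines.
#' @keywords internal
check_emotion <- function(emotion) {
  if (!is.character(emotion) || length(emotion) != 1L || !emotion %in% EMOTIONS) {
    stop("'emotion' must be one of: ", paste(EMOTIONS, collapse = ", "),
         call. = FALSE)
  }
  emotion
}

#' Default emoticon inventory
#'
#' Builds the default emoticon-to-emotion map: 95 synthetic emoticon tokens
#' (`E1` ... `E95`) split across the four emotion classes in canonical order
#' (24, 24, 24 and 23 tokens respectively). Real deployments replace this
#' with a manually annotated inventory via [read_emoticon_map()].
#'
#' @param n_emoticons Total number of emoticon tokens (default 95).
#' @return A data.frame with columns `emoticon` and `emotion`.
#' @examples
#' map <- default_emoticon_map()
#' table(map$emotion)
#' @export
default_emoticon_map <- function(n_emoticons = 95L) {
  n_emoticons <- as.integer(n_emoticons)
  stopifnot(n_emoticons >= 4L)
  # stable blocks per class rather than interleaved tokens
  emotion <- EMOTIONS[sort(rep_len(seq_along(EMOTIONS), n_emoticons))]
  data.frame(
    emoticon = paste0("E", seq_len(n_emoticons)),
    emotion = emotion,
    stringsAsFactors = FALSE
  )
}

#' Read / write an emoticon map
#'
#' The on-disk format is a two-column tab-separated file with a header:
#' `emoticon<TAB>emotion`. Every emoticon must map to exactly one emotion.
#'
#' @param path File path.
#' @return `read_emoticon_map()` returns a data.frame with columns
#'   `emoticon`, `emotion`; `write_emoticon_map()` returns `path` invisibly.
#' @export
read_emoticon_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("emoticon", "emotion") %in% names(map))) {
    stop("emoticon map must have columns 'emoticon' and 'emotion': ", path,
         call. = FALSE)
  }
  validate_emoticon_map(map)
}

#' @rdname read_emoticon_map
#' @param map A data.frame with columns `emoticon`, `emotion`.
#' @export
write_emoticon_map <- function(map, path) {
  validate_emoticon_map(map)
  utils::write.table(map[, c("emoticon", "emotion")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_emoticon_map <- function(map) {
  if (nrow(map) == 0L) stop("emoticon map is empty", call. = FALSE)
  if (anyDuplicated(map$emoticon)) {
    stop("emoticon map assigns some emoticon to more than one emotion",
         call. = FALSE)
  }
  bad <- setdiff(unique(map$emotion), EMOTIONS)
  if (length(bad)) {
    stop("unknown emotion(s) in map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map
}
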