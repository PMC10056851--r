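# 32-bit FNV-1a over a UTF-8 string, done in double arithmetic (exact:
# every intermediate stays below 2^53 by splitting the multiply).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    # h * 16777619 mod 2^32, via 16-bit split
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

bitwXor32 <- function(a, b) {
  # a < 2^32 may exceed .Machine$integer.max; xor via 16-bit halves
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(as.integer(alo), as.integer(blo)) +
    65536 * bitwXor(as.integer(ahi), as.integer(bhi))
}

# deterministic content hash of the canonicalized annotation tuple
clip_id <- function(source_file, start_s, end_s, class_label) {
  fnv1a32(sprintf("%s|%.6f|%.6f|%s", source_file, start_s, end_s, class_label))
}

#' Parse an annotation CSV
#'
#' One row per annotated call: start/end time in seconds, class label and
#' the source recording's file name.  Column names follow the documented
#' default schema (`start_s`, `end_s`, `label`, `source_file`) and can be
#' remapped through `col_map` for other conventions.  Each annotation gets
#' a deterministic `clip_id`, a content hash of its canonicalized
#' `(source_file, start_s, end_s, label)` tuple.
#'
#' @param path path to the CSV file.
#' @param col_map named character vector mapping the canonical names
#'   `start_s`, `end_s`, `label`, `source_file` to the file's column names.
#' @param single_label_only drop rows whose label field holds several
#'   labels (separated by `multi_label_sep`).
#' @param multi_label_sep separator marking multi-label rows.
#' @return a `data.frame` with columns `source_file`, `start_s`, `end_s`,
#'   `class_label`, `clip_id`.
#' @export
parse_annotations <- function(path,
                              col_map = c(start_s = "start_s", end_s = "end_s",
                                          label = "label", source_file = "source_file"),
                              single_label_only = FALSE,
                              multi_label_sep = ";") {
  if (!file.exists(path)) stop("annotation CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("start_s", "end_s", "label", "source_file")
  miss <- setdiff(need, names(col_map))
  if (length(miss)) stop("col_map misses entries for: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(col_map[need]), names(df))
  if (length(absent))
    stop("annotation CSV misses required column(s): ", paste(absent, collapse = ", "))

  start_s <- suppressWarnings(as.numeric(df[[col_map["start_s"]]]))
  end_s <- suppressWarnings(as.numeric(df[[col_map["end_s"]]]))
  bad <- which(!is.finite(start_s) | !is.finite(end_s))
  if (length(bad))
    stop("unparseable timestamp in annotation row ", bad[1L])
  bad <- which(!(start_s >= 0 & start_s < end_s))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) in annotation row ", bad[1L])
  label <- as.character(df[[col_map["label"]]])
  src <- as.character(df[[col_map["source_file"]]])

  keep <- rep(TRUE, nrow(df))
  if (single_label_only)
    keep <- !grepl(multi_label_sep, label, fixed = TRUE)
  out <- data.frame(source_file = src[keep], start_s = start_s[keep],
                    end_s = end_s[keep], class_label = label[keep],
                    stringsAsFactors = FALSE)
  out$clip_id <- mapply(clip_id, out$source_file, out$start_s, out$end_s,
                        out$class_label, USE.NAMES = FALSE)
  out
}

#' Write annotations (or a dataset manifest) as CSV
#'
#' Emits the documented default schema so the file round-trips through
#' [parse_annotations()].
#'
#' @param ann a data.frame with columns `source_file`, `start_s`, `end_s`,
#'   `class_label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(start_s = ann$start_s, end_s = ann$end_s,
                    label = ann$class_label, source_file = ann$source_file)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
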