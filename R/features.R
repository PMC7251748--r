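## Feature-table plumbing: tokens/manifest -> per-token feature rows,
## and feature CSV round-trips for the CLI.

#' Extract feature rows from tokens or a manifest
#'
#' For each token computes the requested feature blocks: CSIFs columns
#' `p_1..p_N` and/or OSPP columns `df_1..df_N`, plus the metadata columns
#' `source_id`, `consonant`, `label`.
#'
#' @param x a list of [speech_token]s, or a manifest `data.frame`
#'   (columns `path`, `consonant`, `label`) whose WAVs are read on the fly.
#' @param features character subset of `c("csifs", "ospp")`.
#' @param n_frames frames per token N (default 10).
#' @param config a [pf_config].
#' @return a `data.frame`, one row per token.
#' @export
extract_features <- function(x, features = c("csifs", "ospp"),
                             n_frames = 10L, config = pf_config()) {
  features <- match.arg(features, several.ok = TRUE)
  if (is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i)
      read_wav(x$path[i], consonant = x$consonant[i], label = x$label[i]))
  }
  rows <- lapply(x, function(tok) {
    row <- data.frame(source_id = tok$source_id,
                      consonant = ifelse(is.na(tok$consonant), "",
                                         tok$consonant),
                      label = tok$label, stringsAsFactors = FALSE)
    if ("csifs" %in% features) {
      p <- csifs_feature(tok, n_frames, config)$p
      row[paste0("p_", seq_len(n_frames))] <- as.list(p)
    }
    if ("ospp" %in% features) {
      df <- ospp_feature(tok, n_frames, config)$DF
      row[paste0("df_", seq_len(n_frames))] <- as.list(df)
    }
    row
  })
  do.call(rbind, rows)
}

#' Feature matrix for one feature set
#'
#' Selects the CSIFs block (`p_*`), the OSPP block (`df_*`) or their
#' concatenation from a feature table and returns the pieces the detector
#' consumes.
#'
#' @param feats a `data.frame` from [extract_features()] (or read back
#'   from its CSV).
#' @param set `"csifs"`, `"ospp"` or `"both"`.
#' @return list with `x` (numeric matrix), `labels`, `consonants`.
#' @export
feature_matrix <- function(feats, set = c("both", "csifs", "ospp")) {
  set <- match.arg(set)
  cols <- switch(set,
    csifs = grep("^p_", names(feats), value = TRUE),
    ospp = grep("^df_", names(feats), value = TRUE),
    both = grep("^(p|df)_", names(feats), value = TRUE))
  if (!length(cols))
    stop("feature table has no columns for set '", set, "'", call. = FALSE)
  list(x = as.matrix(feats[cols]), labels = feats$label,
       consonants = feats$consonant)
}
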