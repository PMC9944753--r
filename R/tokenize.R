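# Token-sequence construction for the EHR transformer: vocabulary with
# special tokens, visit-grouped tokenization of pre-entry histories, and
# masked-sequence corruption for the self-supervised objective.

SPECIAL_TOKENS <- c("[PAD]", "[MASK]", "[UNK]", "[SEP]", "[CLS]")
SEX_TOKENS <- c("SEX_F", "SEX_M")
SMOKING_TOKENS <- c("SMOK_never", "SMOK_former", "SMOK_current", "SMOK_unknown")

#' Build the model vocabulary
#'
#' Indices are contiguous from 1: the five special tokens, sex tokens,
#' smoking-status tokens, then every observed code in lexicographic order.
#' Identical corpora give identical index maps.
#'
#' @param codes Character vector of observed diagnosis/medication codes
#'   (duplicates allowed), or an events tibble with a `code` column.
#' @return A list of class `ehr_vocabulary` with `index` (named integer
#'   vector), `size`, and the id sets `pad_id`, `mask_id`, `unk_id`,
#'   `sep_id`, `cls_id`, `code_ids`.
#' @export
build_vocabulary <- function(codes) {
  if (is.data.frame(codes)) codes <- codes$code
  if (length(codes) == 0) {
    abort("Cannot build a vocabulary from an empty corpus.",
          class = "ehrtmle_data_error")
  }
  toks <- c(SPECIAL_TOKENS, SEX_TOKENS, SMOKING_TOKENS,
            sort(unique(as.character(codes))))
  index <- setNames(seq_along(toks), toks)
  structure(list(index = index, size = length(toks),
                 pad_id = index[["[PAD]"]], mask_id = index[["[MASK]"]],
                 unk_id = index[["[UNK]"]], sep_id = index[["[SEP]"]],
                 cls_id = index[["[CLS]"]],
                 code_ids = unname(index[sort(unique(as.character(codes)))])),
            class = "ehr_vocabulary")
}

vocab_lookup <- function(vocab, tokens) {
  id <- vocab$index[tokens]
  id[is.na(id)] <- vocab$unk_id
  unname(id)
}

#' Tokenize one patient's pre-entry history
#'
#' Events strictly before `entry_day` are grouped into visits by day and
#' ordered chronologically; visits are separated by `[SEP]`. The sequence is
#' prefixed by `[CLS]`, a sex token and a smoking-status token. If the
#' sequence exceeds `max_len`, the oldest events are dropped (the prefix
#' block is always kept). Ages are integer years at each token's day (the
#' prefix uses age at entry); segments alternate 1/2 by visit; positions are
#' visit-order indices.
#'
#' @param patient Per-patient list with `sex`, `smoking`, `birth_day` and an
#'   `events` tibble (`day`, `code`).
#' @param entry_day Study entry day.
#' @param vocab An `ehr_vocabulary`.
#' @param max_len Maximum sequence length in tokens.
#' @return A list of class `token_sequence` with aligned integer vectors
#'   `tokens`, `ages`, `segments`, `positions`, `mem_labels` (all `NA` until
#'   [mask_tokens()]), and `pid`.
#' @export
tokenize_history <- function(patient, entry_day, vocab, max_len = 256L) {
  smok <- patient$smoking
  smok_tok <- if (is.null(smok) || is.na(smok)) "SMOK_unknown" else paste0("SMOK_", smok)
  prefix <- vocab_lookup(vocab, c("[CLS]", paste0("SEX_", patient$sex), smok_tok))
  age_entry <- as.integer((entry_day - patient$birth_day) %/% DAYS_PER_YEAR)

  ev <- patient$events
  ev <- ev[ev$day < entry_day, , drop = FALSE]
  ev <- ev[order(ev$day, ev$code), , drop = FALSE]
  if (nrow(ev) == 0) {
    return(structure(list(tokens = prefix, ages = rep(age_entry, 3L),
                          segments = rep(1L, 3L), positions = rep(0L, 3L),
                          mem_labels = rep(NA_integer_, 3L),
                          pid = patient$pid %||% NA_character_),
                     class = "token_sequence"))
  }
  visit <- cumsum(!duplicated(ev$day))
  n_vis <- max(visit)
  toks <- integer(0); ages <- integer(0); segs <- integer(0); poss <- integer(0)
  for (v in seq_len(n_vis)) {
    idx <- which(visit == v)
    ids <- vocab_lookup(vocab, ev$code[idx])
    a <- as.integer((ev$day[idx][1] - patient$birth_day) %/% DAYS_PER_YEAR)
    if (v < n_vis) ids <- c(ids, vocab$sep_id)
    toks <- c(toks, ids)
    ages <- c(ages, rep(a, length(ids)))
    segs <- c(segs, rep(((v - 1L) %% 2L) + 1L, length(ids)))
    poss <- c(poss, rep(v, length(ids)))
  }
  keep <- max_len - 3L
  if (length(toks) > keep) {
    sel <- (length(toks) - keep + 1L):length(toks)
    toks <- toks[sel]; ages <- ages[sel]; segs <- segs[sel]; poss <- poss[sel]
  }
  structure(list(tokens = c(prefix, toks),
                 ages = c(rep(age_entry, 3L), pmin(pmax(ages, 0L), 110L)),
                 segments = c(rep(1L, 3L), segs),
                 positions = c(rep(0L, 3L), poss),
                 mem_labels = rep(NA_integer_, 3L + length(toks)),
                 pid = patient$pid %||% NA_character_),
            class = "token_sequence")
}

#' Corrupt a token sequence for masked-sequence pretraining
#'
#' Each diagnosis/medication code token is selected independently with
#' probability `mask_rate`; selected tokens are replaced by `[MASK]` (80%),
#' a random code (10%) or kept unchanged (10%). `mem_labels` records the
#' original id at selected slots. Special, sex and smoking tokens are never
#' masked.
#'
#' @param seq A `token_sequence`.
#' @param mask_rate Selection probability in `[0, 1]`.
#' @param seed Seed making the corruption deterministic.
#' @param vocab The `ehr_vocabulary` used to tokenize.
#' @return The corrupted `token_sequence` with `mem_labels` filled.
#' @export
mask_tokens <- function(seq, mask_rate, seed, vocab) {
  stopifnot(mask_rate >= 0, mask_rate <= 1)
  with_seed(seed, {
    cand <- which(seq$tokens %in% vocab$code_ids)
    sel <- cand[runif(length(cand)) < mask_rate]
    seq$mem_labels <- rep(NA_integer_, length(seq$tokens))
    if (length(sel)) {
      seq$mem_labels[sel] <- seq$tokens[sel]
      r <- runif(length(sel))
      seq$tokens[sel[r < 0.8]] <- vocab$mask_id
      repl <- sel[r >= 0.8 & r < 0.9]
      if (length(repl)) {
        seq$tokens[repl] <- sample(vocab$code_ids, length(repl), replace = TRUE)
      }
    }
    seq
  })
}
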