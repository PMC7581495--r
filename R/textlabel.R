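# Weak-supervision labeling from case text: keyword/hashtag rule tables map
# free text to tissue type, disease state, and stain group; a lexicon flags
# marker-test mentions; covariates are encoded with explicit missingness.

#' Construct a case-text object
#'
#' Bundles the post text, any reply texts, and hashtags (normalized: leading
#' `#` stripped, lowercased) for rule-based labeling.
#'
#' @param post_text Single string (may be empty).
#' @param reply_texts Character vector of reply texts.
#' @param hashtags Character vector of hashtags, with or without `#`.
#' @return Object of class `hp_case_text`.
#' @export
case_text <- function(post_text = "", reply_texts = character(), hashtags = character()) {
  structure(list(
    post_text = as.character(post_text %||% ""),
    reply_texts = as.character(reply_texts),
    hashtags = tolower(sub("^#", "", as.character(hashtags)))
  ), class = "hp_case_text")
}

#' Load a keyword rule table
#'
#' Plain-text format, one rule per line: `pattern TAB target TAB priority`.
#' Lines starting with `#` are comments. Patterns match case-insensitively on
#' word boundaries; a `re:` prefix marks a raw regular expression. Lower
#' priority numbers are consulted first.
#'
#' @param path Path to the rule file. The package ships defaults under
#'   `inst/extdata` (`rules_tissue.tsv`, `rules_disease.tsv`,
#'   `rules_stain.tsv`).
#' @return Tibble with columns `pattern`, `target`, `priority`, `regex`,
#'   `n_words`.
#' @export
load_rule_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    abort(paste0("malformed rule table '", path, "' at line(s) ",
                 paste(bad, collapse = ", "),
                 ": expected 'pattern<TAB>target<TAB>priority'"),
          class = "histoprox_config_error")
  }
  tbl <- tibble::tibble(
    pattern = purrr::map_chr(parts, 1L),
    target = purrr::map_chr(parts, 2L),
    priority = as.numeric(purrr::map_chr(parts, 3L))
  )
  if (anyNA(tbl$priority)) {
    abort(paste0("malformed rule table '", path, "': non-numeric priority"),
          class = "histoprox_config_error")
  }
  tbl$regex <- ifelse(
    startsWith(tbl$pattern, "re:"),
    paste0("\\b", sub("^re:", "", tbl$pattern), "\\b"),
    paste0("\\b",
           gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(tbl$pattern)),
           "\\b")
  )
  tbl$n_words <- stringr::str_count(tbl$pattern, "\\S+")
  tbl
}

default_rules <- function(which = c("tissue", "disease", "stain")) {
  which <- match.arg(which)
  load_rule_table(system.file("extdata", paste0("rules_", which, ".tsv"),
                              package = "histoprox", mustWork = TRUE))
}

#' Default marker lexicon
#'
#' @return Character vector of marker terms (raw-regex entries keep their
#'   `re:` prefix).
#' @export
default_marker_lexicon <- function() {
  lines <- readLines(system.file("extdata", "marker_lexicon.txt",
                                 package = "histoprox", mustWork = TRUE),
                     warn = FALSE)
  lines[!grepl("^\\s*(#|$)", lines)]
}

# documents of one case, in priority order: hashtags first, then post, replies
case_documents <- function(text) {
  if (is.character(text)) text <- case_text(post_text = paste(text, collapse = " "))
  stopifnot(inherits(text, "hp_case_text"))
  docs <- list()
  if (length(text$hashtags) > 0L) {
    docs <- c(docs, list(list(text = paste(text$hashtags, collapse = " "),
                              is_hashtag = TRUE)))
  }
  docs <- c(docs, list(list(text = text$post_text, is_hashtag = FALSE)))
  for (r in text$reply_texts) docs <- c(docs, list(list(text = r, is_hashtag = FALSE)))
  docs
}

# matches of a rule table in one document; multi-word matches suppress any
# single/shorter-word match whose pattern is a substring of theirs
match_rules_in_doc <- function(doc_text, rules) {
  s <- tolower(doc_text)
  hit <- purrr::map_lgl(rules$regex, function(rx) {
    stringr::str_detect(s, stringr::regex(rx))
  })
  m <- rules[hit, , drop = FALSE]
  if (nrow(m) > 1L) {
    longer <- m$pattern[m$n_words > 1L]
    if (length(longer) > 0L) {
      contained <- purrr::map_lgl(seq_len(nrow(m)), function(i) {
        any(longer != m$pattern[i] &
              stringr::str_detect(longer, stringr::coll(m$pattern[i])))
      })
      m <- m[!contained, , drop = FALSE]
    }
  }
  m
}

# majority vote across documents, then priority, then MISSING (NA)
vote_label <- function(text, rules) {
  docs <- case_documents(text)
  votes <- character(0)
  best_prio <- list()
  for (d in docs) {
    m <- match_rules_in_doc(d$text, rules)
    if (nrow(m) == 0L) next
    # within a document: hashtag docs already come first in doc order;
    # the document votes for its highest-priority (lowest number) match,
    # multi-word rules outranking shorter ones at equal priority
    m <- m[order(m$priority, -m$n_words), , drop = FALSE]
    votes <- c(votes, m$target[1L])
    p <- m$priority[1L] - (if (d$is_hashtag) 0.5 else 0)  # hashtags outrank text
    cur <- best_prio[[m$target[1L]]]
    best_prio[[m$target[1L]]] <- min(p, cur %||% Inf)
  }
  if (length(votes) == 0L) return(NA_character_)
  tab <- sort(table(votes), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  prios <- purrr::map_dbl(top, function(t) best_prio[[t]] %||% Inf)
  if (sum(prios == min(prios)) == 1L) return(top[which.min(prios)])
  NA_character_
}

#' Parse tissue type, disease state, or stain group from case text
#'
#' Rules fire case-insensitively on word boundaries; hashtags are consulted
#' before free text; each document (hashtags, post, each reply) casts one
#' vote for its highest-priority match (multi-word patterns outrank their
#' substrings, so "carcinoma in situ" beats "carcinoma"); conflicts are
#' resolved by majority across documents, then by rule priority; remaining
#' ties and rule-less cases return `NA` (missing).
#'
#' @param text An [case_text()] object or character vector.
#' @param rules A rule table from [load_rule_table()]; defaults to the
#'   packaged tables.
#' @return A single canonical label or `NA_character_`.
#' @export
parse_tissue <- function(text, rules = default_rules("tissue")) {
  check_rule_targets(rules, tissue_types())
  vote_label(text, rules)
}

#' @rdname parse_tissue
#' @export
parse_disease <- function(text, rules = default_rules("disease")) {
  check_rule_targets(rules, disease_states())
  vote_label(text, rules)
}

#' @rdname parse_tissue
#' @export
parse_stain <- function(text, rules = default_rules("stain")) {
  check_rule_targets(rules, stain_types())
  vote_label(text, rules)
}

check_rule_targets <- function(rules, vocab) {
  bad <- setdiff(unique(rules$target), vocab)
  if (length(bad) > 0L) {
    abort(paste0("rule table targets outside canonical vocabulary: ",
                 paste(bad, collapse = ", "), "; allowed: ",
                 paste(vocab, collapse = ", ")),
          class = "histoprox_config_error")
  }
  invisible(rules)
}

#' Detect a marker-test mention
#'
#' TRUE iff any lexicon term appears (word-boundary, case-insensitive) in the
#' post or reply texts or hashtags.
#'
#' @inheritParams parse_tissue
#' @param lexicon Character vector of terms; `re:`-prefixed entries are raw
#'   regexes. Defaults to [default_marker_lexicon()].
#' @return Logical scalar.
#' @export
detect_marker <- function(text, lexicon = default_marker_lexicon()) {
  docs <- case_documents(text)
  all_text <- tolower(paste(purrr::map_chr(docs, "text"), collapse = " \n "))
  rx <- ifelse(startsWith(lexicon, "re:"),
               paste0("\\b", sub("^re:", "", lexicon), "\\b"),
               paste0("\\b",
                      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                           tolower(lexicon)),
                      "\\b"))
  any(purrr::map_lgl(rx, function(r) stringr::str_detect(all_text, stringr::regex(r))))
}

#' Construct validated case labels
#'
#' @param tissue One of [tissue_types()] or `NA`.
#' @param disease One of [disease_states()] or `NA`.
#' @param marker_mention Logical.
#' @param stain One of [stain_types()] or `NA`.
#' @param acceptable Logical; whether the image is an acceptable pathology
#'   photomicrograph.
#' @return Object of class `hp_case_labels` (a named list).
#' @export
case_labels <- function(tissue = NA_character_, disease = NA_character_,
                        marker_mention = FALSE, stain = NA_character_,
                        acceptable = TRUE) {
  if (!is.na(tissue) && !tissue %in% tissue_types()) {
    abort(paste0("unknown tissue '", tissue, "'; canonical types: ",
                 paste(tissue_types(), collapse = ", ")),
          class = "histoprox_config_error")
  }
  if (!is.na(disease) && !disease %in% disease_states()) {
    abort(paste0("unknown disease state '", disease, "'; canonical states: ",
                 paste(disease_states(), collapse = ", ")),
          class = "histoprox_config_error")
  }
  if (!is.na(stain) && !stain %in% stain_types()) {
    abort(paste0("unknown stain '", stain, "'; canonical stains: ",
                 paste(stain_types(), collapse = ", ")),
          class = "histoprox_config_error")
  }
  structure(list(tissue = tissue, disease = disease,
                 marker_mention = isTRUE(marker_mention), stain = stain,
                 acceptable = isTRUE(acceptable)),
            class = "hp_case_labels")
}

#' Label a case from its text
#'
#' Convenience wrapper running [parse_tissue()], [parse_disease()],
#' [parse_stain()], and [detect_marker()] on one case.
#'
#' @inheritParams parse_tissue
#' @return An `hp_case_labels` object.
#' @export
label_case <- function(text) {
  case_labels(tissue = parse_tissue(text), disease = parse_disease(text),
              marker_mention = detect_marker(text), stain = parse_stain(text))
}

#' Encode clinical covariates
#'
#' Tissue type becomes a one-hot vector over the canonical ten-type order;
#' a missing tissue is all zeros with the `tissue_missing` flag set (the
#' neural encoder consumes the zeros, the forest consumes missing values).
#' Marker mention is a single bit.
#'
#' @param labels An `hp_case_labels` object (or anything with `$tissue` and
#'   `$marker_mention`).
#' @return List with `tissue_onehot` (named length-10 0/1 vector),
#'   `tissue_missing` (logical), `marker` (0/1).
#' @export
encode_covariates <- function(labels) {
  tissue <- labels$tissue
  onehot <- setNames(rep(0, 10L), tissue_types())
  missing <- is.na(tissue)
  if (!missing) {
    if (!tissue %in% tissue_types()) {
      abort(paste0("unknown tissue '", tissue, "'; canonical types: ",
                   paste(tissue_types(), collapse = ", ")),
            class = "histoprox_config_error")
    }
    onehot[tissue] <- 1
  }
  list(tissue_onehot = onehot, tissue_missing = missing,
       marker = as.numeric(isTRUE(labels$marker_mention)))
}

#' Parse labels for every case in a manifest
#'
#' @param manifest Tibble from [load_manifest()] (columns `id`, `text`,
#'   `hashtags`, optional `replies`).
#' @param tissue_rules,disease_rules,stain_rules Rule tables.
#' @param marker_lexicon Marker term lexicon.
#' @return The manifest with columns `tissue`, `disease`, `stain`,
#'   `marker_mention` added (existing gold columns are kept under their
#'   original names).
#' @export
label_cases <- function(manifest,
                        tissue_rules = default_rules("tissue"),
                        disease_rules = default_rules("disease"),
                        stain_rules = default_rules("stain"),
                        marker_lexicon = default_marker_lexicon()) {
  parsed <- purrr::map(seq_len(nrow(manifest)), function(i) {
    ct <- case_text(
      post_text = manifest$text[i] %||% "",
      reply_texts = if ("replies" %in% names(manifest)) unlist(manifest$replies[i]) else character(),
      hashtags = unlist(manifest$hashtags[i])
    )
    tibble::tibble(
      tissue = parse_tissue(ct, tissue_rules),
      disease = parse_disease(ct, disease_rules),
      stain = parse_stain(ct, stain_rules),
      marker_mention = detect_marker(ct, marker_lexicon)
    )
  })
  dplyr::bind_cols(manifest, dplyr::bind_rows(parsed))
}
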