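#' Item codebook for binary questionnaire recoding
#'
#' A codebook describes how each raw questionnaire item is turned into the
#' {0,1} coding the Ising model requires. Knowledge-type items are answered
#' yes/no or know/don't-know and are scored correct = 1; stigma items are
#' answered on a 4-point Likert scale and dichotomized to
#' endorsement/non-endorsement. The `key` column states which raw pole maps
#' to 1 after recoding, so reverse-worded items are handled per item rather
#' than by guesswork.
#'
#' @param item_id character vector of unique item labels (e.g. `"MHKQ1"`,
#'   `"Stigma5"`).
#' @param wording item text (free form, only carried through to outputs).
#' @param community community label per item, one of `"knowledge"` or
#'   `"stigma"`.
#' @param response_type one of `"yes_no"`, `"know_dontknow"`, `"likert4"`
#'   per item. Four-point Likert items are only allowed in the stigma
#'   community.
#' @param key `"positive"` or `"negative"` per item: which raw pole is coded
#'   1. For yes/no items, `positive` means "Yes" is the keyed (correct or
#'   endorsed) answer; `negative` means "No" is.
#'
#' @return A data frame of class `item_codebook`.
#' @export
item_codebook <- function(item_id, wording = item_id,
                          community = c("knowledge", "stigma"),
                          response_type = c("yes_no", "know_dontknow", "likert4"),
                          key = "positive") {
  p <- length(item_id)
  cb <- data.frame(
    item_id = as.character(item_id),
    wording = rep_len(as.character(wording), p),
    community = rep_len(as.character(community), p),
    response_type = rep_len(as.character(response_type), p),
    key = rep_len(as.character(key), p),
    stringsAsFactors = FALSE
  )
  validate_codebook(cb)
}

validate_codebook <- function(cb) {
  required <- c("item_id", "wording", "community", "response_type", "key")
  missing_cols <- setdiff(required, names(cb))
  if (length(missing_cols) > 0)
    stop("codebook is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cb$item_id))
    stop("codebook item_ids must be unique; duplicated: ",
         paste(unique(cb$item_id[duplicated(cb$item_id)]), collapse = ", "))
  bad_comm <- setdiff(cb$community, c("knowledge", "stigma"))
  if (length(bad_comm) > 0)
    stop("unknown community label(s): ", paste(bad_comm, collapse = ", "))
  bad_rt <- setdiff(cb$response_type, c("yes_no", "know_dontknow", "likert4"))
  if (length(bad_rt) > 0)
    stop("unknown response_type(s): ", paste(bad_rt, collapse = ", "))
  bad_key <- setdiff(cb$key, c("positive", "negative"))
  if (length(bad_key) > 0)
    stop("unknown key(s): ", paste(bad_key, collapse = ", "))
  if (any(cb$response_type == "likert4" & cb$community != "stigma"))
    stop("likert4 items are only allowed in the stigma community")
  class(cb) <- c("item_codebook", "data.frame")
  cb
}

#' Read an item codebook from CSV or JSON
#'
#' @param path file path; format is chosen by extension (`.csv` or `.json`).
#' @return An `item_codebook` data frame.
#' @export
read_codebook <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cb <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE),
    stop("unsupported codebook format: ", ext)
  )
  validate_codebook(cb)
}

#' Write an item codebook
#'
#' @param cb an `item_codebook`.
#' @param path destination; `.csv` or `.json` by extension.
#' @export
write_codebook <- function(cb, path) {
  cb <- validate_codebook(as.data.frame(cb))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(cb, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(cb, path, dataframe = "rows", pretty = TRUE)
  } else stop("unsupported codebook format: ", ext)
  invisible(path)
}

#' Recode one raw item response vector to {0,1}
#'
#' Yes/no and know/don't-know items map the keyed (correct) pole to 1 and
#' everything else, including "don't know", to 0. Four-point Likert items
#' are delegated to [dichotomize_likert()].
#'
#' @param raw raw response vector. For `yes_no`: `"Yes"`/`"No"`; for
#'   `know_dontknow`: `"Know"`/`"Don't know"`; for `likert4`: integers 1-4.
#'   Matching is case-insensitive for the text types.
#' @param response_type `"yes_no"`, `"know_dontknow"` or `"likert4"`.
#' @param key `"positive"` or `"negative"`; which pole is coded 1.
#' @param agree_codes for `likert4` items, the raw codes that mean
#'   agree/strongly agree (default `c(1, 2)`, i.e. 1 = strongly agree ...
#'   4 = strongly disagree).
#' @return Integer vector of 0/1.
#' @export
recode_item <- function(raw, response_type, key = "positive", agree_codes = c(1L, 2L)) {
  if (!response_type %in% c("yes_no", "know_dontknow", "likert4"))
    stop("unknown response_type: ", response_type)
  if (!key %in% c("positive", "negative"))
    stop("unknown key: ", key)
  if (response_type == "likert4")
    return(dichotomize_likert(raw, key = key, agree_codes = agree_codes))

  raw_norm <- tolower(trimws(as.character(raw)))
  domain <- switch(response_type,
    yes_no = c(yes = "yes", no = "no"),
    know_dontknow = c(yes = "know", no = "don't know")
  )
  bad <- !raw_norm %in% domain
  if (any(bad))
    stop("out-of-domain value(s) for ", response_type, " item: ",
         paste(unique(raw[bad]), collapse = ", "))
  hit <- raw_norm == domain[["yes"]]
  # for know/don't-know items "don't know" is always 0; a negative key would
  # mean the keyed correct pole is "don't know", which still scores knowing
  # the fact as 0
  if (key == "positive") as.integer(hit) else as.integer(!hit)
}

#' Dichotomize a 4-point Likert item to endorsement
#'
#' Agree and strongly agree become 1 (endorsement), disagree and strongly
#' disagree become 0. Which numeric codes mean "agree" is a convention of
#' the raw data and is configurable; the default is
#' 1 = strongly agree ... 4 = strongly disagree, so codes 1-2 endorse.
#' Items keyed `negative` are complemented after dichotomization.
#'
#' @param raw integer vector with values in 1..4.
#' @inheritParams recode_item
#' @return Integer vector of 0/1.
#' @export
dichotomize_likert <- function(raw, key = "positive", agree_codes = c(1L, 2L)) {
  raw <- as.integer(raw)
  bad <- is.na(raw) | raw < 1L | raw > 4L
  if (any(bad))
    stop("likert4 values must be in 1..4; offending value(s): ",
         paste(unique(raw[bad]), collapse = ", "))
  if (!all(agree_codes %in% 1:4) || length(agree_codes) != 2)
    stop("agree_codes must be two values in 1..4")
  endorsed <- as.integer(raw %in% agree_codes)
  if (identical(key, "negative")) endorsed <- 1L - endorsed
  endorsed
}
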