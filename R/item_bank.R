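#' Anchored rating-scale item banks
#'
#' An item bank holds previously calibrated (anchored) parameters of a Rasch
#' rating scale questionnaire: one overall difficulty `delta` per item, in
#' logits, and a single set of category threshold offsets `taus` shared by all
#' items (the rating-scale constraint). With `m` thresholds every item is
#' scored in `m + 1` ordered categories; the step difficulty of item `i` at
#' step `j` -- the point on the latent scale where categories `j - 1` and `j`
#' are equally probable -- is `delta_i + tau_j`.
#'
#' @name item_bank
NULL

#' Construct an item bank
#'
#' @param items data frame with columns `item_id` (character, unique),
#'   `delta` (finite numeric, logits) and optionally `category` (one-letter
#'   domain code) and `text` (item wording).
#' @param taus numeric vector of strictly increasing shared category threshold
#'   offsets (logits).
#' @param metadata named list of provenance (e.g. `name`, `reliability`,
#'   `pop_mean`, `pop_sd`).
#' @param steps optional matrix (items x thresholds) of printed per-item step
#'   difficulties, kept for validation against `delta + tau`.
#' @return object of class `rsm_bank` with fields `items`, `taus`,
#'   `n_categories` (= `length(taus) + 1`), `metadata`, `steps`.
#' @export
new_bank <- function(items, taus, metadata = list(), steps = NULL) {
  stopifnot(is.data.frame(items), all(c("item_id", "delta") %in% names(items)))
  items$item_id <- as.character(items$item_id)
  items$delta <- as.numeric(items$delta)
  if (anyDuplicated(items$item_id))
    stop("item_id values must be unique within a bank", call. = FALSE)
  if (!all(is.finite(items$delta)))
    stop("all item difficulties must be finite", call. = FALSE)
  taus <- as.numeric(taus)
  if (length(taus) < 1L || !all(is.finite(taus)))
    stop("taus must be a non-empty finite numeric vector", call. = FALSE)
  if (is.unsorted(taus, strictly = TRUE))
    stop("taus must be strictly increasing", call. = FALSE)
  if (!is.null(steps)) {
    steps <- as.matrix(steps)
    stopifnot(nrow(steps) == nrow(items), ncol(steps) == length(taus))
    rownames(steps) <- items$item_id
  }
  structure(
    list(items = items, taus = taus, n_categories = length(taus) + 1L,
         metadata = metadata, steps = steps),
    class = "rsm_bank"
  )
}

#' @export
print.rsm_bank <- function(x, ...) {
  nm <- x$metadata$name
  cat(sprintf("Rasch rating-scale item bank%s\n",
              if (is.null(nm)) "" else paste0(" '", nm, "'")))
  cat(sprintf("  %d items, %d response categories (0..%d)\n",
              nrow(x$items), x$n_categories, x$n_categories - 1L))
  cat(sprintf("  delta range [%.2f, %.2f]; taus: %s\n",
              min(x$items$delta), max(x$items$delta),
              paste(format(x$taus), collapse = ", ")))
  invisible(x)
}

#' The packaged IPQ-18 bank
#'
#' The anchored bank of the 18-item inpatient perception questionnaire:
#' overall difficulties as calibrated, shared thresholds
#' (-3.76, -1.91, 1.57, 4.11) recovered as the common step-minus-overall
#' offsets, five response categories (scores 0--4), and calibration metadata
#' (person separation reliability 0.94, person mean 2.64, SD 2.09). The
#' printed per-item step difficulties are retained in `$steps` so the
#' rating-scale reconstruction can be audited with [validate_bank()].
#'
#' @return an `rsm_bank` with 18 items.
#' @export
#' @examples
#' bank <- builtin_ipq18()
#' step_difficulty(bank, "11", 4)  # 5.69
builtin_ipq18 <- function() {
  tab <- .ipq18_table()
  new_bank(
    items = tab[, c("item_id", "category", "text", "delta")],
    taus = c(-3.76, -1.91, 1.57, 4.11),
    metadata = list(name = "IPQ-18", reliability = 0.94,
                    pop_mean = 2.64, pop_sd = 2.09),
    steps = as.matrix(tab[, c("step1", "step2", "step3", "step4")])
  )
}

# IPQ-18 anchored calibration, ordered by overall difficulty.
.ipq18_table <- function() {
  txt <- c(
    "39|L|Did staff tell you about medication side effects when going home?|3.78|0.02|1.87|5.35|7.89",
    "41|L|Did doctors or nurses give your family information needed to help you?|2.76|-1.00|0.85|4.33|6.87",
    "27|N|Did hospital staff talk about your worries and fears?|2.22|-1.54|0.31|3.79|6.33",
    "11|W|Were you ever bothered by noise at night from other patients?|1.58|-2.18|-0.33|3.15|5.69",
    "24|N|Were you involved in decisions about your care and treatment?|0.67|-3.09|-1.24|2.24|4.78",
    "30|N|How long was it after using the call button before you got the help you needed?|0.42|-3.34|-1.49|1.99|4.53",
    "42|L|Did staff tell you how to contact them if worries arose after leaving?|-0.30|-4.06|-2.21|1.27|3.81",
    "9|A|Did you feel you waited a long time to get to a bed on a ward?|-0.63|-4.39|-2.54|0.94|3.48",
    "44|O|How would you rate how well the doctors and nurses worked together?|-0.71|-4.47|-2.62|0.86|3.40",
    "2|A|How organized was the care you received in the emergency room?|-0.95|-4.71|-2.86|0.62|3.16",
    "5|A|Were you given enough notice of your date of admission?|-1.08|-4.84|-2.99|0.49|3.03",
    "12|W|Were you bothered by noise at night from hospital staff?|-1.10|-4.86|-3.01|0.47|3.01",
    "17|D|Did you have confidence and trust in the doctors treating you?|-1.10|-4.86|-3.01|0.47|3.01",
    "23|N|Did staff say one thing and something quite different happened to you?|-1.10|-4.86|-3.01|0.47|3.01",
    "38|L|Did staff explain the purpose of the medicines so that you could understand?|-1.10|-4.86|-3.01|0.47|3.01",
    "18|D|Did doctors talk in front of you as if you weren't there?|-1.12|-4.88|-3.03|0.45|2.99",
    "19|N|Did you get answers that you could understand from a nurse?|-1.12|-4.88|-3.03|0.45|2.99",
    "34|P|Did hospital staff do everything they could to help you control your pain?|-1.12|-4.88|-3.03|0.45|2.99"
  )
  parts <- strsplit(txt, "|", fixed = TRUE)
  out <- data.frame(
    item_id = vapply(parts, `[`, "", 1L),
    category = vapply(parts, `[`, "", 2L),
    text = vapply(parts, `[`, "", 3L),
    delta = as.numeric(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  for (j in 1:4)
    out[[paste0("step", j)]] <- as.numeric(vapply(parts, `[`, "", 4L + j))
  out
}

#' Load an item bank from JSON or CSV
#'
#' JSON is the canonical serialization: an object with `name`,
#' `n_categories`, `thresholds`, `metadata` and an `items` array of
#' `{id, category, text, delta[, steps]}`. The CSV convenience dialect has
#' header `item_id,category,text,delta,step1..stepM`; the shared thresholds
#' are recovered as the mean per-step offset `step_j - delta_i`, and every
#' item's own offsets must agree with the shared set within `tol`
#' (rating-scale consistency). Typographic minus signs (en dash, Unicode
#' minus) are normalized to ASCII on ingest.
#'
#' @param source path to the bank file.
#' @param format `"json"` or `"csv"`; defaults to the file extension.
#' @param tol consistency tolerance in logits for CSV per-item steps.
#' @return validated `rsm_bank`.
#' @export
load_bank <- function(source, format = c("auto", "json", "csv"), tol = 0.02) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv" else "json"
  bank <- switch(format,
    json = .load_bank_json(source),
    csv = .load_bank_csv(source, tol)
  )
  rep <- validate_bank(bank, tol = tol)
  if (!rep$pass)
    stop("bank failed validation: ", rep$message, call. = FALSE)
  bank
}

.normalize_minus <- function(x) {
  # en dash U+2013, em dash U+2014, true minus U+2212
  gsub("[–—−]", "-", x)
}

.load_bank_json <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop("malformed JSON bank file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (f in c("thresholds", "items"))
    if (is.null(obj[[f]]))
      stop("JSON bank missing required field '", f, "'", call. = FALSE)
  it <- as.data.frame(obj$items)
  if (is.null(it$id) || is.null(it$delta))
    stop("JSON bank items need 'id' and 'delta' fields", call. = FALSE)
  items <- data.frame(item_id = as.character(it$id),
                      delta = as.numeric(it$delta),
                      stringsAsFactors = FALSE)
  items$category <- if (!is.null(it$category)) as.character(it$category) else NA_character_
  items$text <- if (!is.null(it$text)) as.character(it$text) else NA_character_
  steps <- if (!is.null(it$steps)) do.call(rbind, it$steps) else NULL
  md <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
  if (!is.null(obj$name)) md$name <- obj$name
  bank <- new_bank(items[, c("item_id", "category", "text", "delta")],
                   taus = as.numeric(obj$thresholds), metadata = md,
                   steps = steps)
  if (!is.null(obj$n_categories) && obj$n_categories != bank$n_categories)
    stop("declared n_categories (", obj$n_categories,
         ") inconsistent with ", length(bank$taus), " thresholds", call. = FALSE)
  bank
}

.load_bank_csv <- function(path, tol) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                         check.names = FALSE)
  need <- c("item_id", "delta")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CSV bank missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stepcols <- grep("^step[0-9]+$", names(raw), value = TRUE)
  if (!length(stepcols))
    stop("CSV bank needs step1..stepM columns to recover shared thresholds",
         call. = FALSE)
  stepcols <- stepcols[order(as.integer(sub("step", "", stepcols)))]
  num <- function(v) as.numeric(.normalize_minus(as.character(v)))
  delta <- num(raw$delta)
  if (anyNA(delta))
    stop("non-numeric delta in CSV row(s) ",
         paste(which(is.na(delta)), collapse = ", "), call. = FALSE)
  steps <- sapply(stepcols, function(cn) num(raw[[cn]]))
  steps <- matrix(steps, nrow = nrow(raw))
  offsets <- steps - delta  # per-item threshold offsets
  taus <- colMeans(offsets)
  dev <- abs(sweep(offsets, 2L, taus))
  if (any(dev > tol)) {
    bad <- which(dev > tol, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "per-item steps inconsistent with shared thresholds (item %s, step %d, deviation %.3f > tol %.3f)",
      raw$item_id[bad[1L]], bad[2L], dev[bad[1L], bad[2L]], tol), call. = FALSE)
  }
  items <- data.frame(item_id = as.character(raw$item_id), delta = delta,
                      stringsAsFactors = FALSE)
  items$category <- if (!is.null(raw$category)) as.character(raw$category) else NA_character_
  items$text <- if (!is.null(raw$text)) as.character(raw$text) else NA_character_
  new_bank(items, taus = taus, metadata = list(name = basename(path)),
           steps = steps)
}

#' Serialize an item bank to canonical JSON
#'
#' @param bank an `rsm_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "rsm_bank"))
  items <- lapply(seq_len(nrow(bank$items)), function(i) {
    rec <- list(id = bank$items$item_id[i],
                category = bank$items$category[i],
                text = bank$items$text[i],
                delta = bank$items$delta[i])
    if (!is.null(bank$steps)) rec$steps <- unname(bank$steps[i, ])
    rec
  })
  obj <- list(name = bank$metadata$name,
              n_categories = bank$n_categories,
              thresholds = bank$taus,
              metadata = bank$metadata[setdiff(names(bank$metadata), "name")],
              items = items)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a bank's rating-scale structure
#'
#' Checks that thresholds are strictly increasing and, when printed per-item
#' step difficulties are attached, that every step equals `delta_i + tau_j`
#' within `tol` logits.
#'
#' @param bank an `rsm_bank`.
#' @param tol reconstruction tolerance in logits.
#' @return list of class `rsm_validation`: `pass` flag, `message`,
#'   `taus_increasing` flag, and a `steps` data frame with per-item-step
#'   printed value, reconstruction and absolute deviation (empty when the
#'   bank carries no printed steps).
#' @export
validate_bank <- function(bank, tol = 0.01) {
  stopifnot(inherits(bank, "rsm_bank"))
  inc <- !is.unsorted(bank$taus, strictly = TRUE)
  steps_df <- data.frame(item_id = character(), step = integer(),
                         printed = numeric(), reconstructed = numeric(),
                         abs_diff = numeric(), stringsAsFactors = FALSE)
  if (!is.null(bank$steps)) {
    recon <- outer(bank$items$delta, bank$taus, `+`)
    steps_df <- data.frame(
      item_id = rep(bank$items$item_id, times = length(bank$taus)),
      step = rep(seq_along(bank$taus), each = nrow(bank$items)),
      printed = as.vector(bank$steps),
      reconstructed = as.vector(recon),
      stringsAsFactors = FALSE
    )
    steps_df$abs_diff <- abs(steps_df$printed - steps_df$reconstructed)
  }
  ok_steps <- nrow(steps_df) == 0L || all(steps_df$abs_diff <= tol)
  pass <- inc && ok_steps
  msg <- if (pass) "ok" else if (!inc) "thresholds not strictly increasing"
         else sprintf("%d step difficulties deviate from delta + tau by more than %.3g logits",
                      sum(steps_df$abs_diff > tol), tol)
  structure(list(pass = pass, message = msg, taus_increasing = inc,
                 steps = steps_df, tol = tol),
            class = "rsm_validation")
}

#' @export
print.rsm_validation <- function(x, ...) {
  cat(sprintf("Bank validation: %s (%s)\n", if (x$pass) "PASS" else "FAIL",
              x$message))
  if (nrow(x$steps))
    cat(sprintf("  %d step reconstructions checked, max |deviation| %.4f logits\n",
                nrow(x$steps), max(x$steps$abs_diff)))
  invisible(x)
}

#' Step (Rasch-Andrich threshold) difficulty of one item
#'
#' @param bank an `rsm_bank`.
#' @param item_id item identifier.
#' @param j step index in `1..length(taus)`.
#' @return `delta_i + tau_j`, in logits.
#' @export
step_difficulty <- function(bank, item_id, j) {
  stopifnot(inherits(bank, "rsm_bank"))
  ix <- match(as.character(item_id), bank$items$item_id)
  if (is.na(ix)) stop("unknown item_id '", item_id, "'", call. = FALSE)
  if (!(j %in% seq_along(bank$taus)))
    stop("step index ", j, " out of range 1..", length(bank$taus), call. = FALSE)
  bank$items$delta[ix] + bank$taus[j]
}

# internal: delta lookup with error on miss
.bank_deltas <- function(bank, item_ids) {
  ix <- match(as.character(item_ids), bank$items$item_id)
  if (anyNA(ix))
    stop("unknown item_id(s): ",
         paste(item_ids[is.na(ix)], collapse = ", "), call. = FALSE)
  bank$items$delta[ix]
}
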