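#' Load a BITSEA instrument definition
#'
#' The Brief Infant-Toddler Social and Emotional Assessment has 42 items on
#' a 0/1/2 scale: 31 problem-side items and 11 social-competence items. The
#' analysis domains are internalizing, externalizing, dysregulation and
#' competence; problem items outside those three problem domains carry the
#' `other_problem` label. Exactly two dysregulation items concern sleep
#' ("Wakes up at night and needs help to fall asleep again", "Has trouble
#' falling asleep or staying asleep") and are flagged so a
#' sleep-items-removed dysregulation score can be formed.
#'
#' The BITSEA item content is proprietary, so the packaged default mapping
#' (`bitsea_items_synthetic.tsv`) is a synthetic stand-in that honors every
#' structural constraint (item counts, domain sizes, the two sleep items);
#' holders of the licensed instrument can supply their own file in the same
#' format.
#'
#' @param path Tab-delimited instrument file with columns `item_id`, `text`,
#'   `domain`, `is_sleep_item`; defaults to the packaged synthetic mapping.
#' @return Object of class `bitsea_instrument`: a tibble of items, validated.
#' @export
load_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bitsea_items_synthetic.tsv",
                        package = "overlapgaze")
  }
  df <- tibble::as_tibble(read_tsv_file(path))
  needed <- c("item_id", "text", "domain", "is_sleep_item")
  check_that(all(needed %in% names(df)),
             paste("instrument file must have columns:",
                   paste(needed, collapse = ", ")))
  df$is_sleep_item <- as.logical(as.integer(df$is_sleep_item))
  validate_instrument(df)
  structure(df, class = c("bitsea_instrument", class(df)))
}

bitsea_domains <- c("internalizing", "externalizing", "dysregulation",
                    "competence", "other_problem")

validate_instrument <- function(items) {
  check_that(nrow(items) == 42,
             paste0("instrument must have exactly 42 items, found ",
                    nrow(items)))
  check_that(!anyDuplicated(items$item_id), "duplicated item_id")
  check_that(all(items$domain %in% bitsea_domains),
             "unknown domain label in instrument")
  n_comp <- sum(items$domain == "competence")
  check_that(n_comp == 11,
             paste0("instrument must have exactly 11 competence items, found ",
                    n_comp))
  check_that(sum(items$domain != "competence") == 31,
             "instrument must have exactly 31 problem-side items")
  sleep <- items[items$is_sleep_item, ]
  check_that(nrow(sleep) == 2 && all(sleep$domain == "dysregulation"),
             "exactly 2 sleep items are required, both in dysregulation")
  invisible(items)
}

#' Score BITSEA responses into analysis domains
#'
#' Sums the 0/1/2 item responses within each analysis domain
#' (internalizing, externalizing, dysregulation, competence) and adds the
#' dysregulation variant with the two sleep items removed, which guards the
#' night-awakening group comparison against circularity.
#'
#' Missing responses: with `missing = "complete"` (default) a domain score
#' is `NA` unless every item of the domain was answered; with
#' `missing = "impute"` person-mean imputation within the domain is applied
#' when at most 25% of the domain's items are missing.
#'
#' @param responses Data frame with a `participant_id` column and one 0/1/2
#'   column per `item_id` of the instrument (NA allowed).
#' @param instrument A [load_instrument()] object.
#' @param missing `"complete"` or `"impute"`.
#' @return Tibble: `participant_id`, `internalizing`, `externalizing`,
#'   `dysregulation`, `competence`, `dysregulation_no_sleep`.
#' @export
score_domains <- function(responses, instrument, missing = c("complete", "impute")) {
  missing <- match.arg(missing)
  stopifnot(inherits(instrument, "bitsea_instrument"))
  check_that("participant_id" %in% names(responses),
             "`responses` must have a participant_id column")
  absent <- setdiff(instrument$item_id, names(responses))
  check_that(length(absent) == 0,
             paste("response table lacks item columns:",
                   paste(absent, collapse = ", ")))
  resp <- as.matrix(responses[, instrument$item_id, drop = FALSE])
  bad <- which(!is.na(resp) & !(resp %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("out-of-range response for participant ",
         responses$participant_id[bad[1, 1]], ", item ",
         instrument$item_id[bad[1, 2]],
         " (responses must be 0, 1 or 2)", call. = FALSE)
  }

  domain_sum <- function(item_ids) {
    sub <- resp[, item_ids, drop = FALSE]
    k <- length(item_ids)
    n_miss <- rowSums(is.na(sub))
    raw <- rowSums(sub, na.rm = TRUE)
    if (missing == "complete") {
      raw[n_miss > 0] <- NA_real_
    } else {
      person_mean <- rowMeans(sub, na.rm = TRUE)
      imputed <- raw + n_miss * person_mean
      raw <- ifelse(n_miss == 0, raw,
                    ifelse(n_miss / k <= 0.25, imputed, NA_real_))
    }
    raw
  }

  ids <- function(dom) instrument$item_id[instrument$domain == dom]
  dys_no_sleep_ids <- instrument$item_id[instrument$domain == "dysregulation" &
                                           !instrument$is_sleep_item]
  tibble::tibble(
    participant_id = responses$participant_id,
    internalizing = domain_sum(ids("internalizing")),
    externalizing = domain_sum(ids("externalizing")),
    dysregulation = domain_sum(ids("dysregulation")),
    competence = domain_sum(ids("competence")),
    dysregulation_no_sleep = domain_sum(dys_no_sleep_ids)
  )
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of one domain:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`,
#' computed over complete respondents.
#'
#' @param items Numeric matrix or data frame, respondents x items.
#' @return Alpha (scalar).
#' @examples
#' set.seed(1)
#' z <- rnorm(200)
#' m <- sapply(1:5, function(i) z + rnorm(200))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  check_that(k >= 2, "alpha needs at least 2 items")
  check_that(nrow(m) >= 2, "alpha needs at least 2 complete respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("total score has zero variance; alpha undefined", call. = FALSE)
  }
  (k / (k - 1)) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Per-domain reliability of a response table
#'
#' @param responses Response table as in [score_domains()].
#' @param instrument A [load_instrument()] object.
#' @return Tibble: `domain`, `alpha`, `n_items`.
#' @export
domain_alphas <- function(responses, instrument) {
  doms <- c("internalizing", "externalizing", "dysregulation", "competence")
  dplyr::bind_rows(lapply(doms, function(d) {
    item_ids <- instrument$item_id[instrument$domain == d]
    tibble::tibble(domain = d,
                   alpha = cronbach_alpha(responses[, item_ids]),
                   n_items = length(item_ids))
  }))
}
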