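#' The seven Wellness Check life domains
#'
#' The Wellness Check asks, on a 0-10 wellness scale (10 = best), how well the
#' user is doing despite cardiac pain in seven domains of life. The domain set
#' mirrors the interference domains of the Brief Pain Inventory, reversed to a
#' wellness orientation.
#'
#' @return character vector of the 7 domain codes, in canonical order.
#' @export
wellness_domains <- function() {
  c(
    "general_activities", "work", "walking", "mood",
    "relations", "sleep", "enjoyment"
  )
}

#' Wellness Check record
#'
#' @param user_id opaque identifier.
#' @param scores named numeric vector or list with exactly the seven
#'   [wellness_domains()], each an integer in 0-10 (10 = best wellness).
#' @param asked_at ISO-8601 UTC timestamp.
#' @return object of class `wellness_check`.
#' @export
wellness_check <- function(user_id, scores, asked_at) {
  stopifnot(is.character(user_id), length(user_id) == 1)
  scores <- unlist(scores)
  doms <- wellness_domains()
  if (is.null(names(scores)) || !setequal(names(scores), doms) ||
    length(scores) != length(doms)) {
    stop("scores must cover exactly the 7 wellness domains: ",
      paste(doms, collapse = ", "),
      call. = FALSE
    )
  }
  scores <- scores[doms]
  if (any(is.na(scores)) || any(scores != as.integer(scores)) ||
    any(scores < 0) || any(scores > 10)) {
    stop("wellness scores must be integers in [0, 10]", call. = FALSE)
  }
  structure(
    list(
      user_id = user_id, scores = as.integer(scores),
      asked_at = parse_utc(asked_at)
    ),
    class = "wellness_check"
  )
}

#' @rdname as.list.event_profile
#' @export
as.list.wellness_check <- function(x, ...) {
  list(
    user_id = x$user_id,
    scores = as.list(stats::setNames(x$scores, wellness_domains())),
    asked_at = format_utc(x$asked_at)
  )
}

#' Flag wellness domains at or below the content threshold
#'
#' A domain is flagged iff its score is `<= threshold` (default 4, the
#' published cut-off: the boundary score of exactly 4 *is* flagged). Flagged
#' domains drive library-content selection; a check with all-excellent scores
#' flags nothing and triggers no content.
#'
#' @param check a [wellness_check()].
#' @param threshold integer in 0-10.
#' @return character vector of flagged domain codes (canonical order).
#' @export
flag_domains <- function(check, threshold = 4) {
  stopifnot(inherits(check, "wellness_check"), length(threshold) == 1,
    threshold >= 0, threshold <= 10)
  doms <- wellness_domains()
  doms[check$scores <= threshold]
}

#' Validate a library content index
#'
#' @param items data.frame (or path to a JSON/CSV file) with columns
#'   `item_id`, `kind` (article|lay_summary|video|podcast), `domains`
#'   (list-column of domain codes, or a single `;`-separated string), `title`.
#' @return data.frame of class `library_index` with a list-column `domains`.
#' @export
library_index <- function(items) {
  if (is.character(items) && length(items) == 1) {
    items <- if (grepl("\\.csv$", items)) {
      utils::read.csv(items, stringsAsFactors = FALSE)
    } else {
      jsonlite::fromJSON(items, simplifyDataFrame = TRUE)
    }
  }
  items <- as.data.frame(items)
  req <- c("item_id", "kind", "domains", "title")
  if (!all(req %in% names(items))) {
    stop("library index needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!is.list(items$domains)) {
    items$domains <- strsplit(as.character(items$domains), "[;,]\\s*")
  }
  items$domains <- lapply(items$domains, canonicalize_code)
  if (anyDuplicated(items$item_id)) stop("duplicate item_id in library", call. = FALSE)
  kinds <- c("article", "lay_summary", "video", "podcast")
  if (!all(items$kind %in% kinds)) {
    stop("library kind must be one of: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  bad <- !vapply(items$domains, function(d) {
    length(d) > 0 && all(d %in% wellness_domains())
  }, logical(1))
  if (any(bad)) {
    stop("library items with empty or unknown domain tags: ",
      paste(items$item_id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  class(items) <- c("library_index", "data.frame")
  items
}

#' Recommend library content for flagged wellness domains
#'
#' Selects every library item addressing at least one flagged domain, ordered
#' by the number of flagged domains it covers (descending), ties broken by
#' `item_id` (ascending) -- a deterministic ordering. No flagged domains, no
#' items. An empty library with flagged domains yields an empty
#' recommendation plus a warning (content gap, not a caller error).
#'
#' @param flagged character vector of flagged domain codes (from
#'   [flag_domains()]).
#' @param library a [library_index()].
#' @return list of class `wellness_recommendation`: `flagged_domains`,
#'   `items` (ordered character vector of item ids).
#' @export
recommend_content <- function(flagged, library) {
  stopifnot(inherits(library, "library_index"))
  flagged <- sort(unique(canonicalize_code(flagged)))
  bad <- setdiff(flagged, wellness_domains())
  if (length(bad) > 0) stop("unknown wellness domain(s): ", paste(bad, collapse = ", "), call. = FALSE)
  items <- character(0)
  if (length(flagged) > 0) {
    if (nrow(library) == 0) {
      warning("library is empty; no content available for flagged domains",
        call. = FALSE
      )
    } else {
      coverage <- vapply(
        library$domains,
        function(d) length(intersect(d, flagged)), integer(1)
      )
      hit <- coverage > 0
      ids <- library$item_id[hit]
      items <- ids[order(-coverage[hit], ids)]
    }
  }
  structure(
    list(flagged_domains = flagged, items = items),
    class = "wellness_recommendation"
  )
}

#' @export
print.wellness_recommendation <- function(x, ...) {
  if (length(x$flagged_domains) == 0) {
    cat("No wellness domains flagged; no content recommended.\n")
  } else {
    cat("Flagged domains:", paste(x$flagged_domains, collapse = ", "), "\n")
    cat("Recommended items:", paste(x$items, collapse = ", "), "\n")
  }
  invisible(x)
}
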