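#' Read a forum-post export table
#'
#' Reads a delimited forum export (one row per original post or comment) and
#' materializes it as a tibble of raw posts. Original posts and the comments
#' they accrue are handled uniformly as "posts". Rows whose text is empty or
#' whitespace-only are dropped and counted in the load report; parent ids that
#' do not reference any post id in the file are kept but flagged as dangling.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the roles
#'   `post_id`, `author_id`, `text` (required) and `parent_id`, `timestamp`,
#'   `is_staff` (optional) to column names in the file.
#' @param delim Field delimiter, default `","`.
#'
#' @return A tibble with columns `post_id`, `parent_id`, `author_id`,
#'   `timestamp` (POSIXct, `NA` when unparseable), `text`, `is_staff`, in the
#'   original row order, with attribute `"load_report"` (see [load_report()]).
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,user,body", "p1,u1,hello world", "p2,u2,"), f)
#' posts <- read_forum_table(f,
#'   column_map = c(post_id = "id", author_id = "user", text = "body"))
#' load_report(posts)
#' @export
read_forum_table <- function(path,
                             column_map = c(post_id = "post_id",
                                            author_id = "author_id",
                                            text = "text"),
                             delim = ",") {
  stopifnot(file.exists(path))
  required <- c("post_id", "author_id", "text")
  missing_roles <- setdiff(required, names(column_map))
  if (length(missing_roles) > 0) {
    stop("column_map must name columns for roles: ",
         paste(missing_roles, collapse = ", "))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  for (role in names(column_map)) {
    if (!column_map[[role]] %in% names(raw)) {
      stop("mapped column not found in header: \"", column_map[[role]],
           "\" (role: ", role, ")")
    }
  }
  get_col <- function(role, default = NA_character_) {
    if (role %in% names(column_map)) raw[[column_map[[role]]]] else
      rep(default, nrow(raw))
  }
  posts <- tibble::tibble(
    post_id   = get_col("post_id"),
    parent_id = get_col("parent_id"),
    author_id = get_col("author_id"),
    timestamp = get_col("timestamp"),
    text      = get_col("text"),
    is_staff  = get_col("is_staff")
  )
  posts$parent_id[is.na(posts$parent_id)] <- ""
  posts$text[is.na(posts$text)] <- ""
  posts$is_staff <- tolower(posts$is_staff) %in% c("true", "t", "1", "yes")

  ts <- rep(as.POSIXct(NA), nrow(posts))
  has_ts <- !is.na(posts$timestamp) & nzchar(posts$timestamp)
  if (any(has_ts)) {
    parsed <- as.POSIXct(posts$timestamp[has_ts],
                         tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                        "%Y-%m-%d"),
                         tz = "UTC", optional = TRUE)
    if (anyNA(parsed)) {
      warning(sum(is.na(parsed)),
              " timestamp(s) could not be parsed; kept as NA")
    }
    ts[has_ts] <- parsed
  }
  posts$timestamp <- ts

  if (anyDuplicated(posts$post_id)) {
    stop("post_id values are not unique")
  }

  n_read <- nrow(posts)
  empty <- !nzchar(trimws(posts$text))
  dangling <- posts$parent_id[nzchar(posts$parent_id) &
                                !(posts$parent_id %in% posts$post_id)]
  posts <- posts[!empty, , drop = FALSE]

  attr(posts, "load_report") <- list(
    source = path,
    rows_read = n_read,
    rows_kept = nrow(posts),
    rows_dropped_empty_text = sum(empty),
    dangling_parent_ids = unique(dangling)
  )
  posts
}

#' Retrieve the load report attached by [read_forum_table()]
#'
#' @param posts A tibble returned by [read_forum_table()].
#' @return A list with elements `source`, `rows_read`, `rows_kept`,
#'   `rows_dropped_empty_text` and `dangling_parent_ids`.
#' @export
load_report <- function(posts) {
  attr(posts, "load_report")
}

#' Remove staff and test content
#'
#' Drops every post whose author is on the staff-id list or whose `is_staff`
#' flag is set, preserving the order of the remaining posts. The operation is
#' idempotent. This mechanizes the manual removal of pre-launch test content:
#' an explicit id list makes the filter reproducible.
#'
#' @param posts A tibble of raw posts (see [read_forum_table()]).
#' @param staff_ids Character vector of author ids considered study staff.
#' @return The filtered tibble, original relative order preserved.
#' @export
filter_staff <- function(posts, staff_ids = character()) {
  flag <- if ("is_staff" %in% names(posts)) posts$is_staff else FALSE
  keep <- !(posts$author_id %in% staff_ids) & !flag
  posts[keep, , drop = FALSE]
}

#' Build the dual analysis corpora
#'
#' Splits the filtered posts into the two corpora the downstream stages
#' require: the sentiment-analysis (SA) corpus, in which every semantic
#' element of the verbatim text -- capitalization, punctuation runs,
#' emoticons -- is preserved because the rule-based valence scorer exploits
#' them, and the topic-modeling (TM) corpus, which is initialized verbatim
#' and normalized later by [normalize_and_tokenize()]. Both corpora carry
#' exactly the same post ids in the same order.
#'
#' @param posts Non-empty tibble of filtered posts.
#' @param source Optional provenance string recorded in the object.
#' @return An object of class `dual_corpus`: a list with tibbles `sa` and
#'   `tm` (columns `post_id`, `text`) and a `provenance` list.
#' @export
build_dual_corpus <- function(posts, source = NA_character_) {
  if (nrow(posts) == 0) {
    stop("no posts remain after filtering; nothing to analyze")
  }
  corp <- tibble::tibble(post_id = posts$post_id, text = posts$text)
  structure(
    list(
      sa = corp,
      tm = corp,
      provenance = list(source = source,
                        n_posts = nrow(corp),
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC"))
    ),
    class = "dual_corpus"
  )
}

#' @export
print.dual_corpus <- function(x, ...) {
  cat("<dual_corpus> ", nrow(x$sa), " posts (SA corpus verbatim, ",
      "TM corpus pending normalization)\n", sep = "")
  invisible(x)
}

#' Corpus size statistics
#'
#' Counts posts and whitespace-delimited words over the raw text, the only
#' tokenization primitive applied before normalization. Additive under
#' corpus concatenation.
#'
#' @param posts Tibble of posts with a `text` column.
#' @return A list with integer elements `n_posts` and `n_words`.
#' @examples
#' corpus_stats(tibble::tibble(text = c("hello world", "hi")))
#' @export
corpus_stats <- function(posts) {
  n_words <- if (nrow(posts) == 0) 0L else {
    sum(vapply(strsplit(trimws(posts$text), "\\s+"),
               function(w) length(w[nzchar(w)]), integer(1)))
  }
  list(n_posts = nrow(posts), n_words = as.integer(n_words))
}
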