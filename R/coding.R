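# vocabularies for the raw survey fields
.survey_vocab <- list(
  gender = c("male", "female"),
  residence = c("city", "town", "rural"),
  co_residence = c("household", "alone", "institution"),
  economic_status = c("very_poor", "poor", "so_so", "rich", "very_rich"),
  fruit_freq = c("A", "B", "C", "D"),
  veg_freq = c("A", "B", "C", "D"),
  flavor = c("salty", "bland", "so-so", "sweet", "spicy"),
  smoking_now = c("yes", "no"),
  drinking_now = c("yes", "no"),
  regular_exercise = c("yes", "no"),
  qol_rating = c("A", "B", "C", "D", "E"),
  health_rating = c("A", "B", "C", "D", "E")
)

.behavior_fields <- c("fruit_freq", "veg_freq", "flavor", "smoking_now",
                      "drinking_now", "regular_exercise", "sleep_hours")

#' Apply the analysis-population exclusions
#'
#' Drops, in order: (1) participants under age 65; (2) records missing
#' essential demographics (gender, age, residence); (3) records missing any
#' behavior field (diet, flavor, smoking, drinking, exercise, sleep). Counts
#' removed by each criterion are reported in application order, so they sum
#' to the total attrition.
#'
#' @param table Survey data.frame.
#' @return List with `table` (retained records) and `log` (data.frame of
#'   criterion / n_removed).
#' @export
apply_exclusions <- function(table) {
  miss <- function(x) is.na(x) | (is.character(x) & !is.na(x) & x == "")
  n0 <- nrow(table)
  under_age <- !is.na(table$age) & table$age < 65
  t1 <- table[!under_age, , drop = FALSE]

  demo_miss <- miss(t1$gender) | miss(t1$age) | miss(t1$residence)
  t2 <- t1[!demo_miss, , drop = FALSE]

  beh_miss <- Reduce(`|`, lapply(.behavior_fields, function(f) miss(t2[[f]])))
  t3 <- t2[!beh_miss, , drop = FALSE]

  log <- data.frame(
    criterion = c("age_under_65", "missing_demographics",
                  "missing_behavior_fields"),
    n_removed = c(sum(under_age), sum(demo_miss), sum(beh_miss))
  )
  if (nrow(t3) == 0) warning("all records excluded")
  stopifnot(sum(log$n_removed) == n0 - nrow(t3))
  list(table = t3, log = log)
}

# check a categorical column against its vocabulary; error names the
# offending record and field
check_vocab <- function(x, field, ids) {
  bad <- which(!is.na(x) & !(x %in% .survey_vocab[[field]]))
  if (length(bad))
    stop("coding error: record ", ids[bad[1]], " has out-of-vocabulary ",
         field, " value '", x[bad[1]], "'")
  invisible(TRUE)
}

#' Code raw survey responses into the binary behavior matrix
#'
#' Dichotomization rules: sleep under 6 hours (strictly) is inadequate
#' sleep; fruit or vegetable frequency C or D is insufficient intake;
#' flavor preference 'salty' is a salty diet; current smoking or drinking
#' 'yes' is the behavior; regular exercise 'no' is irregular exercise. All
#' other values code 0.
#'
#' @param table Survey data.frame whose behavior fields are complete
#'   (run [apply_exclusions()] first).
#' @return N x 7 integer 0/1 matrix with the canonical [hrb_behaviors()]
#'   columns; row names are record ids.
#' @export
code_behaviors <- function(table) {
  ids <- if (!is.null(table$id)) table$id else seq_len(nrow(table))
  for (f in setdiff(.behavior_fields, "sleep_hours"))
    check_vocab(table[[f]], f, ids)
  if (any(is.na(table$sleep_hours)) ||
      !is.numeric(table$sleep_hours) || any(table$sleep_hours < 0))
    stop("coding error: sleep_hours must be complete non-negative numeric")
  m <- cbind(
    insufficient_fruit = as.integer(table$fruit_freq %in% c("C", "D")),
    insufficient_vegetable = as.integer(table$veg_freq %in% c("C", "D")),
    salty_diet = as.integer(table$flavor == "salty"),
    smoking = as.integer(table$smoking_now == "yes"),
    drinking = as.integer(table$drinking_now == "yes"),
    irregular_exercise = as.integer(table$regular_exercise == "no"),
    inadequate_sleep = as.integer(table$sleep_hours < 6)
  )
  rownames(m) <- ids
  as_behavior_matrix(m)
}

#' Behavior counts and the co-occurrence indicator
#'
#' @param matrix Binary behavior matrix.
#' @return List with `counts` (per-record row sums), `distribution` (counts
#'   of records at 0..p behaviors), and `prop_multiple` (proportion with two
#'   or more).
#' @export
behavior_count <- function(matrix) {
  m <- as_behavior_matrix(matrix)
  counts <- rowSums(m)
  dist <- tabulate(counts + 1L, nbins = ncol(m) + 1L)
  names(dist) <- 0:ncol(m)
  list(counts = as.integer(counts), distribution = dist,
       prop_multiple = mean(counts >= 2))
}

#' Score the ordinal self-rated outcomes
#'
#' Maps ratings A..E to scores 5..1 for self-rated quality of life and
#' self-rated health. Records missing either rating are dropped from the
#' result (their count is attached as attribute `n_dropped`).
#'
#' @param table Survey data.frame with `qol_rating` and `health_rating`.
#' @return data.frame of `id`, `qol_score`, `health_score` (integers 1-5).
#' @export
score_outcomes <- function(table) {
  ids <- if (!is.null(table$id)) table$id else seq_len(nrow(table))
  keep <- !is.na(table$qol_rating) & !is.na(table$health_rating)
  tab <- table[keep, , drop = FALSE]
  ids <- ids[keep]
  check_vocab(tab$qol_rating, "qol_rating", ids)
  check_vocab(tab$health_rating, "health_rating", ids)
  score <- function(x) 6L - match(x, c("A", "B", "C", "D", "E"))
  out <- data.frame(id = ids, qol_score = score(tab$qol_rating),
                    health_score = score(tab$health_rating))
  attr(out, "n_dropped") <- sum(!keep)
  out
}
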