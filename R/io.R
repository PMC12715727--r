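#' Read a survey table from CSV
#'
#' Reads a UTF-8 CSV with the package's canonical header vocabulary. A
#' column mapping (named character vector `c(foreign = "canonical")`, or a
#' path to a JSON file of the same shape) adapts foreign headers.
#'
#' @param path CSV path.
#' @param mapping Optional column-name mapping.
#' @return data.frame of raw survey records.
#' @export
read_survey <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("cannot read input: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
      mapping <- unlist(jsonlite::read_json(mapping, simplifyVector = TRUE))
    hit <- names(tab) %in% names(mapping)
    names(tab)[hit] <- unname(mapping[names(tab)[hit]])
  }
  tab
}

.required_columns <- c("gender", "age", "residence", "sleep_hours",
                       "fruit_freq", "veg_freq", "flavor", "smoking_now",
                       "drinking_now", "regular_exercise")

#' Validate a survey input file
#'
#' Checks the header vocabulary, categorical domains, and numeric ranges of
#' a survey CSV without mutating the data.
#'
#' @inheritParams read_survey
#' @return List of class `hrb_validation`: `ok` (logical),
#'   `structural_errors` (character), `field_violations` (data.frame of
#'   field / n_violations), `n_records`.
#' @export
validate_input <- function(path, mapping = NULL) {
  structural <- character()
  tab <- tryCatch(read_survey(path, mapping), error = function(e) {
    structural <<- c(structural, conditionMessage(e)); NULL
  })
  if (is.null(tab) || nrow(tab) == 0 || ncol(tab) == 0) {
    if (is.null(structural) || !length(structural))
      structural <- "file is empty or has no data rows"
    return(structure(list(ok = FALSE, structural_errors = structural,
                          field_violations = data.frame(
                            field = character(), n_violations = integer()),
                          n_records = 0L),
                     class = "hrb_validation"))
  }
  missing_cols <- setdiff(.required_columns, names(tab))
  if (length(missing_cols))
    structural <- c(structural,
                    paste("missing columns:",
                          paste(missing_cols, collapse = ", ")))
  viol <- list()
  for (f in intersect(names(.survey_vocab), names(tab))) {
    x <- tab[[f]]
    viol[[f]] <- sum(!is.na(x) & x != "" & !(x %in% .survey_vocab[[f]]))
  }
  for (f in intersect(c("age", "sleep_hours", "education_years"), names(tab))) {
    x <- suppressWarnings(as.numeric(tab[[f]]))
    viol[[f]] <- sum(!is.na(tab[[f]]) & (is.na(x) | x < 0))
  }
  fv <- data.frame(field = names(viol),
                   n_violations = as.integer(unlist(viol)))
  rownames(fv) <- NULL
  structure(list(ok = length(structural) == 0 && sum(fv$n_violations) == 0,
                 structural_errors = structural, field_violations = fv,
                 n_records = nrow(tab)),
            class = "hrb_validation")
}

#' @export
print.hrb_validation <- function(x, ...) {
  cat("Input validation:", if (x$ok) "OK" else "PROBLEMS FOUND",
      "(", x$n_records, "records )\n")
  if (length(x$structural_errors))
    cat("structural:", paste(x$structural_errors, collapse = "; "), "\n")
  bad <- x$field_violations[x$field_violations$n_violations > 0, ]
  if (nrow(bad)) print(bad)
  invisible(x)
}

# weight matrix -> igraph object (undirected, weighted, named)
as_igraph <- function(W, membership = NULL) {
  W <- check_weight_matrix(W)
  if (is.null(colnames(W))) colnames(W) <- rownames(W) <- paste0("V", seq_len(ncol(W)))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(membership))
    g <- igraph::set_vertex_attr(g, "community",
                                 value = as.integer(membership))
  g
}

#' Export a network as GraphML
#'
#' @param W Symmetric weight matrix.
#' @param path Output file.
#' @param membership Optional community ids written as a vertex attribute.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(W, path, membership = NULL) {
  igraph::write_graph(as_igraph(W, membership), path, format = "graphml")
  invisible(path)
}

#' Export a network as a weighted edge list
#'
#' Three-column CSV (node_i, node_j, weight), nonzero edges only.
#'
#' @param W Symmetric weight matrix.
#' @param path Output CSV path.
#' @return Invisibly, the edge-list data.frame.
#' @export
write_edge_list <- function(W, path) {
  W <- check_weight_matrix(W)
  nm <- colnames(W)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(W)))
  pairs <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  el <- data.frame(node_i = nm[pairs[, 1]], node_j = nm[pairs[, 2]],
                   weight = W[pairs])
  write.csv(el, path, row.names = FALSE)
  invisible(el)
}
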