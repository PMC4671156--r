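# Declarative YAML criteria configuration: parsing and validation.

#' Validate a criteria configuration document
#'
#' Resolves a parsed configuration document (a list, typically from
#' [yaml::read_yaml()]) into typed [criterion()] objects plus the
#' output options, collecting *all* validation problems rather than
#' stopping at the first. Each problem message names the offending
#' criterion and field.
#'
#' The document has a `criteria` list (entries with `name`, `column`,
#' `fn`, and the parameters of the matching mapping function: `cuts` or
#' `cuts_quantiles`, `mapping`/`default`, `midpoint`/`steepness`,
#' `des_min`, `des_max`, `scale`, `weight`), an optional `feature_id`
#' key naming the ID column, and an optional `output` section with
#' `threshold` or `k`, and a `comparison` block (`column`, `ascending`,
#' `prefilter` entries of the form `{column, min, max}`).
#'
#' @param doc A list: the parsed configuration document.
#' @return A list with elements `criteria` (list of criterion objects,
#'   empty on failure), `id_col`, `output` (as given) and `errors`
#'   (character vector, empty when the document is valid).
#' @seealso [read_criteria_config()] which reads a file and stops on
#'   errors.
#' @export
validate_criteria_config <- function(doc) {
  errors <- character(0)
  criteria <- list()
  if (!is.list(doc)) {
    return(list(criteria = list(), id_col = "feature_id", output = NULL,
                errors = "configuration document must be a mapping"))
  }
  entries <- doc$criteria
  if (is.null(entries) || !is.list(entries) || length(entries) == 0L) {
    errors <- c(errors, "configuration has no 'criteria' entries")
  } else {
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      label <- if (is.list(e) && !is.null(e$name)) e$name
               else paste0("criteria[", i, "]")
      if (!is.list(e)) {
        errors <- c(errors, paste0(label, ": entry is not a mapping"))
        next
      }
      known <- c("name", "column", "fn", "cuts", "cuts_quantiles",
                 "mapping", "default", "midpoint", "steepness",
                 "des_min", "des_max", "scale", "weight")
      extra <- setdiff(names(e), known)
      if (length(extra) > 0L)
        errors <- c(errors, paste0(label, ": unknown field(s) ",
                                   paste(extra, collapse = ", ")))
      res <- tryCatch({
        args <- e[intersect(names(e), known)]
        if (!is.null(args[["cuts"]]))
          args[["cuts"]] <- as.numeric(unlist(args[["cuts"]]))
        if (!is.null(args[["cuts_quantiles"]]))
          args[["cuts_quantiles"]] <- as.numeric(unlist(args[["cuts_quantiles"]]))
        if (!is.null(args[["mapping"]])) {
          m <- unlist(args[["mapping"]])
          args[["mapping"]] <- stats::setNames(as.numeric(m), names(m))
        }
        do.call(criterion, args)
      }, error = function(err) conditionMessage(err))
      if (inherits(res, "criterion")) criteria <- c(criteria, list(res))
      else errors <- c(errors, paste0(label, ": ", res))
    }
  }
  nm <- vapply(criteria, function(cr) cr$name, character(1))
  if (anyDuplicated(nm))
    errors <- c(errors, paste0("duplicate criterion name(s): ",
                               paste(unique(nm[duplicated(nm)]),
                                     collapse = ", ")))

  output <- doc$output
  if (!is.null(output)) {
    if (!is.null(output$threshold) &&
        (!is.numeric(output$threshold) || output$threshold < 0 ||
         output$threshold > 1))
      errors <- c(errors, "output.threshold must lie in [0, 1]")
    if (!is.null(output$k) && (!is.numeric(output$k) || output$k < 1))
      errors <- c(errors, "output.k must be a positive integer")
    cmp <- output$comparison
    if (!is.null(cmp)) {
      if (is.null(cmp$column))
        errors <- c(errors, "output.comparison needs a 'column'")
      for (pf in cmp$prefilter) {
        if (is.null(pf$column) || (is.null(pf$min) && is.null(pf$max)))
          errors <- c(errors, paste0(
            "output.comparison.prefilter entries need 'column' and ",
            "'min' and/or 'max'"))
      }
    }
  }
  id_col <- if (!is.null(doc$feature_id)) doc$feature_id else "feature_id"
  list(criteria = if (length(errors)) list() else criteria,
       id_col = id_col, output = output, errors = errors)
}

#' Read and validate a criteria configuration file
#'
#' Reads a YAML criteria specification (see
#' [validate_criteria_config()] for the schema) and returns the
#' resolved configuration, stopping with a combined report if the
#' document has any validation problems. The package ships a preset,
#' `system.file("extdata", "breast_cancer_six_criteria.yaml",
#' package = "generank")`, encoding the six-criterion breast-cancer
#' specification; cut points not fixed by the published criteria are
#' encoded as data quantiles to be resolved against the user's table.
#'
#' @param path Path to a YAML configuration file.
#' @return As [validate_criteria_config()], with empty `errors`.
#' @export
read_criteria_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  cfg <- validate_criteria_config(doc)
  if (length(cfg$errors) > 0L)
    stop("invalid criteria configuration (", path, "):\n  - ",
         paste(cfg$errors, collapse = "\n  - "), call. = FALSE)
  cfg
}

prefilter_predicates <- function(prefilter) {
  lapply(prefilter, function(pf) {
    force(pf)
    function(tab) {
      if (!pf$column %in% names(tab))
        stop("prefilter column '", pf$column, "' not found", call. = FALSE)
      v <- tab[[pf$column]]
      keep <- rep(TRUE, length(v))
      if (!is.null(pf$min)) keep <- keep & v >= pf$min
      if (!is.null(pf$max)) keep <- keep & v <= pf$max
      keep
    }
  })
}

#' Read a delimited feature table
#'
#' Reads a CSV or TSV file with a header row. The delimiter is
#' inferred from the file extension (`.csv` vs `.tsv`/`.txt`) unless
#' given explicitly.
#'
#' @param path Path to the file.
#' @param delimiter `","`, `"\t"`, or `NULL` to infer from the
#'   extension.
#' @return A data frame.
#' @export
read_feature_table <- function(path, delimiter = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    ext <- tolower(tools::file_ext(path))
    delimiter <- if (ext == "csv") "," else "\t"
  }
  utils::read.delim(path, sep = delimiter, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_output_table <- function(tab, path, delimiter = NULL) {
  if (is.null(delimiter)) {
    ext <- tolower(tools::file_ext(path))
    delimiter <- if (ext == "csv") "," else "\t"
  }
  utils::write.table(tab, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
}

# Provenance record written alongside every CLI output: the fully
# resolved criteria, the seed, and a digest of the input file.
write_provenance <- function(out_path, criteria = NULL, seed = NULL,
                             inputs = NULL, extra = list()) {
  rec <- c(list(
    tool = "generank",
    version = as.character(utils::packageVersion("generank")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = if (!is.null(inputs))
      lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
    criteria = if (!is.null(criteria))
      lapply(criteria, function(cr) Filter(Negate(is.null), unclass(cr)))
  ), extra)
  path <- paste0(out_path, ".provenance.json")
  jsonlite::write_json(Filter(Negate(is.null), rec), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
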