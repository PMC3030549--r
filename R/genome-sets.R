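#' Construct a group of genome family sets
#'
#' A `genome_sets` object represents a group of genomes, each reduced to the
#' set of gene families it carries. This is the input to every fluidity
#' computation: only family presence/absence matters, so paralogous copies of
#' a family within one genome count once.
#'
#' @param x A named list; each element is a vector of gene-family identifiers
#'   (coerced to character, duplicates collapsed). Names are genome ids and
#'   must be unique and non-empty.
#' @return An object of class `genome_sets`: a named list of character
#'   vectors of distinct family ids.
#' @examples
#' g <- genome_sets(list(A = c("f1", "f2", "f3", "f4"),
#'                       B = c("f1", "f2", "f3", "f5"),
#'                       C = c("f1", "f2", "f6", "f7")))
#' fluidity(g)
#' @export
genome_sets <- function(x) {
  if (!is.list(x) || length(x) == 0) {
    stop("`x` must be a non-empty named list of family-id vectors", call. = FALSE)
  }
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every genome must have a non-empty id (list names)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(x, function(f) unique(as.character(f)))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop("genomes with empty family sets: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  structure(sets, class = "genome_sets")
}

#' @export
print.genome_sets <- function(x, ...) {
  cat("genome_sets:", length(x), "genomes,",
      length(unique(unlist(x, use.names = FALSE))), "distinct families\n")
  m <- lengths(x)
  cat("  families per genome: min", min(m), "median", stats::median(m),
      "max", max(m), "\n")
  invisible(x)
}

#' @export
`[.genome_sets` <- function(x, i) {
  structure(unclass(x)[i], class = "genome_sets")
}

as_genome_sets <- function(x) {
  if (inherits(x, "genome_sets")) x else genome_sets(x)
}

#' Read genome family sets from a TSV file
#'
#' Two layouts are supported. `"membership"` is a long table with columns
#' `genome_id` and `family_id`, one row per family occurrence (duplicate rows
#' collapse to one). `"matrix"` is a presence/absence table whose first
#' column holds genome ids and whose remaining columns, named by family id,
#' hold 0/1 indicators. Lines starting with `#` are metadata and are skipped.
#'
#' @param path Path to a tab-separated file.
#' @param format `"membership"` (default) or `"matrix"`.
#' @return A [genome_sets] object.
#' @export
read_genome_sets <- function(path, format = c("membership", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "membership") {
    df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            colClasses = "character")
    need <- c("genome_id", "family_id")
    if (!all(need %in% names(df))) {
      stop("membership file must have columns genome_id and family_id; found: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
    genome_sets(split(df$family_id, factor(df$genome_id,
                                           levels = unique(df$genome_id))))
  } else {
    df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            check.names = FALSE)
    if (ncol(df) < 2) stop("presence/absence matrix needs >= 2 columns", call. = FALSE)
    gids <- as.character(df[[1]])
    fam <- colnames(df)[-1]
    sets <- lapply(seq_along(gids), function(i) {
      fam[as.numeric(df[i, -1, drop = TRUE]) > 0]
    })
    names(sets) <- gids
    genome_sets(sets)
  }
}

#' Write genome family sets as a membership TSV
#'
#' Writes the long `genome_id<TAB>family_id` layout read by
#' [read_genome_sets()], preceded by `#`-prefixed metadata lines.
#'
#' @param sets A [genome_sets] object.
#' @param path Output path.
#' @param meta Optional named character vector written as `# key: value`
#'   header lines (seeds, parameters, tool version).
#' @return `path`, invisibly.
#' @export
write_genome_sets <- function(sets, path, meta = NULL) {
  sets <- as_genome_sets(sets)
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  writeLines("genome_id\tfamily_id", con)
  for (g in names(sets)) {
    writeLines(paste(g, sets[[g]], sep = "\t"), con)
  }
  invisible(path)
}

write_meta <- function(con, meta) {
  writeLines(sprintf("# fluidity %s",
                     as.character(utils::packageVersion("fluidity"))), con)
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. NULL seed = use current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
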