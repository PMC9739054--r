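#' Construct a field book of augmented-trial observations
#'
#' A field book holds one row per experimental unit of an augmented
#' randomized complete block trial: replicated check genotypes appear once
#' in every block, unreplicated test genotypes appear exactly once overall.
#' Trait observations are stored one column per trait.
#'
#' @param genotype character vector of genotype ids.
#' @param block character or integer vector of block ids.
#' @param is_check logical vector flagging check plots.
#' @param ... one or more named numeric vectors of trait observations.
#' @param treatment optional character label for the stress treatment
#'   (e.g. `"DS"`, `"HS"`).
#' @param validate check the augmented-design invariants (default `TRUE`).
#'
#' @return A data frame of class `"fieldbook"` with columns `genotype`,
#'   `block`, `is_check`, `treatment` and one column per trait; the trait
#'   names are kept in `attr(x, "traits")`.
#' @export
#' @examples
#' fieldbook(genotype = c("C1", "C1", "T1"),
#'           block    = c("B1", "B2", "B1"),
#'           is_check = c(TRUE, TRUE, FALSE),
#'           GY       = c(4.1, 4.5, 3.9))
fieldbook <- function(genotype, block, is_check, ..., treatment = NA_character_,
                      validate = TRUE) {
  traits <- list(...)
  if (length(traits) == 0L)
    stop("at least one trait column is required", call. = FALSE)
  if (is.null(names(traits)) || any(!nzchar(names(traits))))
    stop("trait columns must be named", call. = FALSE)
  n <- length(genotype)
  if (length(block) == 1L) block <- rep_len(block, n)
  if (length(is_check) == 1L) is_check <- rep_len(is_check, n)
  if (length(block) != n || length(is_check) != n)
    stop("genotype, block and is_check must have equal length", call. = FALSE)
  for (tn in names(traits)) {
    traits[[tn]] <- as.numeric(traits[[tn]])
    if (length(traits[[tn]]) != n)
      stop("trait '", tn, "' has wrong length", call. = FALSE)
    if (any(is.infinite(traits[[tn]])))
      stop("trait '", tn, "' contains non-finite values", call. = FALSE)
  }
  fb <- data.frame(genotype = as.character(genotype),
                   block = as.character(block),
                   is_check = as.logical(is_check),
                   treatment = rep_len(as.character(treatment), n),
                   stringsAsFactors = FALSE)
  for (tn in names(traits)) fb[[tn]] <- traits[[tn]]
  attr(fb, "traits") <- names(traits)
  class(fb) <- c("fieldbook", "data.frame")
  if (validate) validate_fieldbook(fb)
  fb
}

#' Trait columns of a field book
#' @param fb a [fieldbook()].
#' @return Character vector of trait names.
#' @export
fieldbook_traits <- function(fb) {
  stopifnot(inherits(fb, "fieldbook"))
  attr(fb, "traits")
}

#' Validate the augmented-design structure of a field book
#'
#' Checks that every check genotype occurs at most once per block and that
#' every test genotype occurs exactly once in the whole trial; a genotype
#' may not be flagged both check and test.
#'
#' @param fb a [fieldbook()].
#' @return `fb`, invisibly; errors describe the violated invariant.
#' @export
validate_fieldbook <- function(fb) {
  stopifnot(inherits(fb, "fieldbook"))
  if (anyNA(fb$is_check))
    stop("is_check flags must not be missing", call. = FALSE)
  mixed <- tapply(fb$is_check, fb$genotype, function(z) length(unique(z)) > 1L)
  if (any(mixed))
    stop("genotype(s) flagged both check and test: ",
         paste(names(mixed)[mixed], collapse = ", "), call. = FALSE)
  chk <- fb[fb$is_check, , drop = FALSE]
  if (nrow(chk)) {
    dup <- duplicated(chk[c("genotype", "block")])
    if (any(dup))
      stop("design violation: check '", chk$genotype[dup][1L],
           "' replicated within block '", chk$block[dup][1L], "'",
           call. = FALSE)
  }
  tst <- fb[!fb$is_check, , drop = FALSE]
  if (nrow(tst)) {
    dup <- duplicated(tst$genotype)
    if (any(dup))
      stop("design violation: test genotype '", tst$genotype[dup][1L],
           "' appears more than once", call. = FALSE)
  }
  invisible(fb)
}

#' @export
print.fieldbook <- function(x, ...) {
  b <- length(unique(x$block))
  cat("Augmented-design field book: ", nrow(x), " plots, ", b, " blocks, ",
      length(unique(x$genotype[x$is_check])), " checks, ",
      length(unique(x$genotype[!x$is_check])), " tests\n", sep = "")
  cat("Traits:", paste(fieldbook_traits(x), collapse = ", "), "\n")
  print.data.frame(head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Read a field book from a delimited text file
#'
#' The file must carry a header with `genotype`, `block` and `is_check`
#' columns (an optional `treatment` column is kept); every remaining column
#' is read as a trait.  Empty cells become missing values.
#'
#' @param path path to a CSV (`.csv`) or TSV file.
#' @param registry optional [trait_registry()]; when supplied, every trait
#'   column must be registered.
#' @param sep field separator; inferred from the extension by default.
#' @return A validated [fieldbook()].
#' @export
read_fieldbook <- function(path, registry = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"))
  need <- c("genotype", "block", "is_check")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("malformed field book header: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  trait_cols <- setdiff(names(raw), c(need, "treatment"))
  if (length(trait_cols) == 0L)
    stop("field book has no trait columns", call. = FALSE)
  if (!is.null(registry)) {
    unreg <- setdiff(trait_cols, registry$trait)
    if (length(unreg))
      stop("trait(s) absent from registry: ", paste(unreg, collapse = ", "),
           call. = FALSE)
  }
  is_check <- raw$is_check
  if (!is.logical(is_check)) {
    is_check <- tolower(as.character(is_check)) %in%
      c("true", "t", "1", "yes", "check")
  }
  args <- c(list(genotype = raw$genotype, block = raw$block,
                 is_check = is_check),
            lapply(raw[trait_cols], as.numeric),
            list(treatment = if ("treatment" %in% names(raw))
              raw$treatment else NA_character_))
  do.call(fieldbook, args)
}

#' Write a field book to a delimited text file
#'
#' @param fb a [fieldbook()].
#' @param path output path; `.csv` selects comma separation, anything else
#'   tab separation.
#' @return `path`, invisibly.
#' @export
write_fieldbook <- function(fb, path) {
  stopifnot(inherits(fb, "fieldbook"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(as.data.frame(fb), path, sep = sep, row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}
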