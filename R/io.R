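#' Read a gene x sample expression matrix
#'
#' Reads a tab-separated expression table: first column gene identifiers,
#' header row of sample identifiers, remaining cells numeric log-scale
#' expression values. Values are expected to be nonnegative (log-scale
#' intensities); negative cells are an error unless `allow_negative = TRUE`.
#'
#' @param path Path to a TSV file.
#' @param allow_negative Permit negative expression values (default `FALSE`;
#'   the downstream proportion-based normalization assumes nonnegative
#'   log-scale input).
#' @param log2p1 Apply `log2(x + 1)` to all values after validation, for
#'   matrices supplied on the linear scale.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample.
#' @seealso [normalize_expression()], [write_table()]
#' @export
read_expression <- function(path, allow_negative = FALSE, log2p1 = FALSE) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2L) {
    stop("expression file must have a gene column and >= 1 sample column",
         call. = FALSE)
  }
  names(df)[1L] <- "gene"
  df <- dplyr::mutate(df, dplyr::across(-"gene", \(x) {
    y <- suppressWarnings(as.numeric(x))
    if (anyNA(y) && !all(is.na(x) == is.na(y))) {
      bad <- x[which(is.na(y) & !is.na(x))[1L]]
      stop("non-numeric expression cell: '", bad, "'", call. = FALSE)
    }
    y
  }))
  if (log2p1) {
    df <- dplyr::mutate(df, dplyr::across(-"gene", \(x) log2(x + 1)))
  }
  validate_expression(df, allow_negative = allow_negative)
}

#' Validate an expression tibble
#'
#' Checks the invariants assumed throughout the package: unique gene and
#' sample identifiers, all-finite numeric values, and (by default)
#' nonnegative log-scale values.
#'
#' @inheritParams read_expression
#' @param expr A tibble as returned by [read_expression()]: `gene` column
#'   plus numeric sample columns.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_expression <- function(expr, allow_negative = FALSE) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  expr <- tibble::as_tibble(expr)
  dup_g <- expr$gene[duplicated(expr$gene)]
  if (length(dup_g) > 0L) {
    stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  samples <- setdiff(names(expr), "gene")
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0L) {
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  m <- expr_values(expr)
  if (!all(is.finite(m))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (!allow_negative && any(m < 0)) {
    stop("negative expression value found; input must be nonnegative ",
         "log-scale (use allow_negative = TRUE to override)", call. = FALSE)
  }
  expr
}

# numeric matrix view of an expression/score tibble (id column -> rownames)
expr_values <- function(df, id_col = "gene") {
  m <- as.matrix(df[setdiff(names(df), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- df[[id_col]]
  m
}

# rebuild a tibble from a matrix + id column name
values_to_tbl <- function(m, id_col = "gene") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(out, !!id_col := rownames(m), .before = 1L)
}

#' Read a GMT gene-set collection
#'
#' Parses the Broad GMT dialect: one gene set per line, fields separated by
#' tabs — set name, description, then member gene identifiers. Duplicate
#' genes within a line are dropped; duplicate set names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble with columns `set`, `description`, `gene`
#'   (one row per set-gene pair).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(tibble::tibble(set = character(), description = character(),
                          gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1L], " has fewer than 3 fields",
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicated gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(fields, \(f) tibble::tibble(
    set = f[[1L]], description = f[[2L]], gene = unique(f[-(1:2)])
  ))
}

# named list of gene vectors from a long gene-set tibble
geneset_list <- function(sets) {
  split(sets$gene, sets$set)
}

#' Read a sample phenotype table
#'
#' Reads a two-column TSV (`sample`, `group`) and normalizes group labels to
#' the canonical `control` / `case` vocabulary. `normal` maps to `control`;
#' `tumor`, `tumour` and `disease` map to `case` (case-insensitively).
#' Every sample in `samples` must be labelled, and both groups must be
#' non-empty.
#'
#' @param path Path to a 2-column TSV (header optional but recommended).
#' @param samples Character vector of sample identifiers that must be
#'   covered (typically the expression matrix columns).
#' @return A tibble with columns `sample` and `group`
#'   (values `"control"` / `"case"`).
#' @export
read_phenotypes <- function(path, samples) {
  if (!file.exists(path)) {
    stop("phenotype file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  # tolerate headerless files
  if (!all(c("sample", "group") %in% tolower(names(df)))) {
    df <- readr::read_tsv(path, col_names = c("sample", "group"),
                          col_types = "cc", progress = FALSE)
  }
  names(df) <- tolower(names(df))
  validate_phenotypes(df[c("sample", "group")], samples)
}

#' Validate and canonicalize a phenotype tibble
#'
#' @param pheno Tibble with columns `sample`, `group`.
#' @inheritParams read_phenotypes
#' @return Canonicalized tibble restricted to `samples`, in their order.
#' @export
validate_phenotypes <- function(pheno, samples) {
  stopifnot(is.data.frame(pheno), all(c("sample", "group") %in% names(pheno)))
  pheno <- tibble::as_tibble(pheno)
  synonyms <- c(control = "control", normal = "control",
                case = "case", tumor = "case", tumour = "case",
                disease = "case")
  grp <- synonyms[tolower(trimws(pheno$group))]
  if (anyNA(grp)) {
    bad <- unique(pheno$group[is.na(grp)])
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected control/case (synonyms: normal, tumor, disease)",
         call. = FALSE)
  }
  pheno$group <- unname(grp)
  if (anyDuplicated(pheno$sample)) {
    stop("duplicated sample(s) in phenotype table: ",
         paste(unique(pheno$sample[duplicated(pheno$sample)]),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(samples, pheno$sample)
  if (length(missing) > 0L) {
    stop("sample(s) missing from phenotype table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pheno <- pheno[match(samples, pheno$sample), , drop = FALSE]
  if (!any(pheno$group == "control")) {
    stop("at least one control sample is required", call. = FALSE)
  }
  if (!any(pheno$group == "case")) {
    stop("at least one case sample is required", call. = FALSE)
  }
  pheno
}

#' Write a result table as TSV
#'
#' Writes any result tibble (enrichment records, clustering assignments,
#' score matrices) as a tab-separated file with a header row. Floating-point
#' columns are rendered with 6 significant digits; row order is preserved as
#' given, so callers arrange deterministically before writing.
#'
#' @param records A data frame. An empty frame yields a header-only file.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- dplyr::mutate(tibble::as_tibble(records), dplyr::across(
    dplyr::where(is.double),
    \(x) trimws(formatC(x, digits = 6L, format = "g"))
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
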