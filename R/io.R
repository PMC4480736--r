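#' Read and write the package's TSV dialect
#'
#' All tabular artifacts use plain TSV with a single header line that begins
#' with `#`. Missing values are encoded as empty fields. [read_ppi_table()]
#' validates strictly against a schema: a wrong column count or a non-numeric
#' value in a numeric column is reported with the offending line, and
#' duplicate keys are rejected.
#'
#' @param path File path.
#' @param schema Named character vector mapping column names to types:
#'   `"c"` character, `"d"` double, `"i"` integer.
#' @param key_cols Optional character vector of columns whose combination
#'   must be unique across rows.
#' @return A tibble with the schema's columns and types.
#' @export
read_ppi_table <- function(path, schema, key_cols = NULL) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) == 0) {
    stop("empty file: ", path, call. = FALSE)
  }
  header <- lines[[1]]
  if (!startsWith(header, "#")) {
    stop("missing '#' header line in ", path, call. = FALSE)
  }
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  if (!identical(cols, names(schema))) {
    stop(
      "header of ", path, " is [", paste(cols, collapse = ", "),
      "], expected [", paste(names(schema), collapse = ", "), "]",
      call. = FALSE
    )
  }
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad before validating widths
  widths <- lengths(fields)
  trailing_na <- widths < length(cols) &
    (body == "" | endsWith(body, "\t"))
  fields[trailing_na] <- lapply(fields[trailing_na], function(f) {
    c(f, rep("", length(cols) - length(f)))
  })
  widths <- lengths(fields)
  bad <- which(widths != length(cols))
  if (length(bad) > 0) {
    stop(
      "line ", bad[[1]] + 1L, " of ", path, " has ", widths[[bad[[1]]]],
      " columns, expected ", length(cols),
      call. = FALSE
    )
  }
  mat <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE)
  out <- vector("list", length(cols))
  names(out) <- cols
  for (j in seq_along(cols)) {
    raw <- mat[, j]
    raw[raw == ""] <- NA_character_
    type <- schema[[j]]
    if (type == "c") {
      out[[j]] <- raw
    } else {
      suppressWarnings(num <- as.numeric(raw))
      bad_num <- which(!is.na(raw) & is.na(num))
      if (length(bad_num) > 0) {
        stop(
          "line ", bad_num[[1]] + 1L, " of ", path,
          ": non-numeric value '", raw[[bad_num[[1]]]],
          "' in column '", cols[[j]], "'",
          call. = FALSE
        )
      }
      out[[j]] <- if (type == "i") as.integer(num) else num
    }
  }
  out <- as_tibble(out)
  if (!is.null(key_cols)) {
    keys <- do.call(paste, c(out[key_cols], sep = "\x1f"))
    if (anyDuplicated(keys)) {
      dup <- which(duplicated(keys))[[1]]
      stop(
        "duplicate key at line ", dup + 1L, " of ", path, ": ",
        gsub("\x1f", " / ", keys[[dup]], fixed = TRUE),
        call. = FALSE
      )
    }
  }
  out
}

#' @rdname read_ppi_table
#' @param x Data frame to write.
#' @export
write_ppi_table <- function(x, path) {
  x <- as_tibble(x)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wb") # "wb": identical bytes on every platform
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  if (nrow(x) > 0) {
    cells <- lapply(x, function(col) {
      s <- if (is.double(col)) {
        vapply(col, format_double, character(1))
      } else {
        as.character(col)
      }
      s[is.na(col)] <- ""
      s
    })
    writeLines(do.call(paste, c(cells, sep = "\t")), con)
  }
  invisible(path)
}

# Shortest decimal representation that round-trips through as.numeric().
format_double <- function(v) {
  if (is.na(v)) {
    return("")
  }
  if (is.infinite(v)) {
    return(if (v > 0) "Inf" else "-Inf")
  }
  for (digits in c(15L, 16L, 17L)) {
    s <- formatC(v, digits = digits, format = "g")
    if (as.numeric(s) == v) {
      return(s)
    }
  }
  s
}

# Schemas for the standard input dialects -------------------------------

schema_interactions <- function() {
  c(protein_a = "c", protein_b = "c", source = "c")
}

schema_annotation <- function() {
  c(protein_id = "c", aspect = "c", term_id = "c")
}

schema_orthologs <- function() {
  c(species = "c", model_protein_id = "c", human_protein_id = "c",
    group_id = "c")
}

schema_domains <- function() {
  c(protein_id = "c", domain_id = "c")
}

schema_ddi <- function() {
  c(domain_a = "c", domain_b = "c", confidence_level = "i")
}

#' Readers for the standard input tables
#'
#' Thin wrappers around [read_ppi_table()] with the fixed schema of each
#' input dialect. Interaction tables carry two identifier columns plus a
#' source label; annotation tables carry protein, aspect (`CC`/`BP`) and a
#' flat term identifier; the expression table carries a `gene_id` column
#' followed by sample columns named `cond1_i` / `cond2_i`.
#'
#' @param path File path.
#' @return A tibble (for [read_expression()], genes in rows and one column
#'   per sample).
#' @export
read_interactions <- function(path) {
  read_ppi_table(path, schema_interactions())
}

#' @rdname read_interactions
#' @export
read_annotation <- function(path) {
  tab <- read_ppi_table(path, schema_annotation())
  bad <- setdiff(unique(tab$aspect), c("CC", "BP"))
  if (length(bad) > 0) {
    stop("unknown annotation aspect(s) in ", path, ": ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tab
}

#' @rdname read_interactions
#' @export
read_orthologs <- function(path) {
  read_ppi_table(path, schema_orthologs())
}

#' @rdname read_interactions
#' @export
read_domains <- function(path) {
  read_ppi_table(path, schema_domains(),
    key_cols = c("protein_id", "domain_id")
  )
}

#' @rdname read_interactions
#' @export
read_ddi <- function(path) {
  read_ppi_table(path, schema_ddi())
}

#' @rdname read_interactions
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 1)
  if (length(lines) == 0 || !startsWith(lines[[1]], "#")) {
    stop("missing '#' header line in ", path, call. = FALSE)
  }
  cols <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  if (cols[[1]] != "gene_id" || length(cols) < 3) {
    stop("expression table must have gene_id plus sample columns: ", path,
      call. = FALSE
    )
  }
  sample_cols <- cols[-1]
  if (!all(grepl("^cond[12]_[0-9]+$", sample_cols))) {
    stop("expression sample columns must be named cond1_i / cond2_i: ", path,
      call. = FALSE
    )
  }
  schema <- c("c", rep("d", length(sample_cols)))
  names(schema) <- cols
  read_ppi_table(path, schema, key_cols = "gene_id")
}

#' @rdname read_interactions
#' @export
read_edge_list <- function(path) {
  read_ppi_table(path, c(protein_a = "c", protein_b = "c"),
    key_cols = c("protein_a", "protein_b")
  )
}

#' Export a network as a SIF edge list
#'
#' Simple interaction format (`node relationship node`) for graph viewers.
#'
#' @param edges Data frame with `protein_a`/`protein_b` columns.
#' @param path Output path.
#' @param relation Relationship label placed in the middle column.
#' @export
write_sif <- function(edges, path, relation = "pp") {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    paste(edges$protein_a, relation, edges$protein_b, sep = "\t"),
    con
  )
  invisible(path)
}

# Convert an expression tibble (gene_id + sample columns) to a matrix.
expression_matrix <- function(expr) {
  stopifnot("gene_id" %in% names(expr))
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene ids in expression table", call. = FALSE)
  }
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

# Condition labels ("cond1"/"cond2") from expression sample column names.
expression_conditions <- function(expr_mat) {
  sub("_[0-9]+$", "", colnames(expr_mat))
}
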