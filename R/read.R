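# Readers and writers for the package's plain-text input formats, and the
# in-memory containers they populate. All identifier comparison is
# case-sensitive after whitespace trimming.

.action_vocab <- list(
  `1`  = c("activate", "agonist", "promote", "+", "+1", "1"),
  `-1` = c("inhibit", "antagonist", "block", "-", "-1", "−1")
)

.normalize_sign <- function(x, what = "action", file = NULL) {
  x <- trimws(tolower(x))
  out <- rep(NA_real_, length(x))
  out[x %in% .action_vocab[["1"]]] <- 1
  out[x %in% .action_vocab[["-1"]]] <- -1
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(sprintf(
      "unrecognized %s '%s'%s (row %d); expected one of: %s",
      what, x[bad], if (is.null(file)) "" else paste0(" in ", file), bad,
      paste(unlist(.action_vocab), collapse = ", ")
    ))
  }
  out
}

.read_tsv <- function(path, required, optional = character()) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  df <- df[, c(required, intersect(optional, names(df))), drop = FALSE]
  df[required] <- lapply(df[required], trimws)
  df
}

#' Read a drug annotation store
#'
#' Assembles the per-drug annotations used by all feature extractors from
#' four headered TSV tables: the drug roster (`drug_id`, `name`, optional
#' `smiles`, optional pipe-separated `atc_codes`), drug–disease links
#' (`drug_id`, `disease_id`), drug–ADR links (`drug_id`, `adr_id`) and
#' signed drug–target links (`drug_id`, `target_id`, `action`). Action
#' strings are mapped onto +1 (promotive) / -1 (inhibitory); any string
#' outside the accepted vocabulary is an error rather than a guess.
#'
#' @param drugs_tsv Path to the drug roster TSV.
#' @param disease_tsv,adr_tsv,target_tsv Paths to the annotation link
#'   tables; `NULL` leaves the corresponding annotation sets empty.
#' @return A `drug_store` object: a list of tibbles `drugs`, `diseases`,
#'   `adrs`, `targets`.
#' @export
read_drug_store <- function(drugs_tsv, disease_tsv = NULL, adr_tsv = NULL,
                            target_tsv = NULL) {
  drugs <- .read_tsv(drugs_tsv, "drug_id", c("name", "smiles", "atc_codes"))
  if (any(drugs$drug_id == "")) abort(sprintf("%s: empty drug_id", drugs_tsv))
  if (anyDuplicated(drugs$drug_id)) {
    dup <- drugs$drug_id[duplicated(drugs$drug_id)][1]
    abort(sprintf("duplicate drug_id '%s' in %s", dup, drugs_tsv))
  }
  if (!"name" %in% names(drugs)) drugs$name <- drugs$drug_id
  if (!"smiles" %in% names(drugs)) drugs$smiles <- NA_character_
  drugs$smiles[!is.na(drugs$smiles) & drugs$smiles == ""] <- NA_character_
  atc_raw <- if (!"atc_codes" %in% names(drugs)) rep("", nrow(drugs)) else {
    ifelse(is.na(drugs$atc_codes), "", drugs$atc_codes)
  }
  atc <- lapply(strsplit(atc_raw, "|", fixed = TRUE),
                function(x) unique(trimws(x[trimws(x) != ""])))
  for (codes in atc) .check_atc(codes)
  drugs <- tibble::tibble(drug_id = drugs$drug_id, name = drugs$name,
                          smiles = drugs$smiles, atc = atc)

  read_links <- function(path, col) {
    if (is.null(path)) {
      return(tibble::tibble(drug_id = character(), !!col := character()))
    }
    df <- .read_tsv(path, c("drug_id", col))
    .check_known_drugs(df$drug_id, drugs$drug_id, path)
    dplyr::distinct(tibble::as_tibble(df))
  }
  diseases <- read_links(disease_tsv, "disease_id")
  adrs <- read_links(adr_tsv, "adr_id")

  targets <- if (is.null(target_tsv)) {
    tibble::tibble(drug_id = character(), target_id = character(),
                   sign = double())
  } else {
    df <- .read_tsv(target_tsv, c("drug_id", "target_id", "action"))
    .check_known_drugs(df$drug_id, drugs$drug_id, target_tsv)
    df$sign <- .normalize_sign(df$action, "action", target_tsv)
    df <- dplyr::distinct(tibble::as_tibble(df[c("drug_id", "target_id", "sign")]))
    conflict <- df |>
      dplyr::count(.data$drug_id, .data$target_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflict) > 0) {
      abort(sprintf("conflicting action signs for drug '%s' on target '%s' in %s",
                    conflict$drug_id[1], conflict$target_id[1], target_tsv))
    }
    df
  }

  structure(list(drugs = drugs, diseases = diseases, adrs = adrs,
                 targets = targets),
            class = "drug_store")
}

#' Construct a drug store from in-memory tables
#'
#' Programmatic counterpart of [read_drug_store()], applying the same
#' validation (unique drug ids, +1/-1 target signs, well-formed ATC
#' codes, links referencing known drugs).
#'
#' @param drugs Tibble/data frame with `drug_id` and optional `name`,
#'   `smiles`, `atc` (list-column of code vectors).
#' @param diseases,adrs Tibbles with `drug_id` and `disease_id` /
#'   `adr_id`.
#' @param targets Tibble with `drug_id`, `target_id`, `sign` (+1/-1).
#' @return A `drug_store`.
#' @export
drug_store <- function(drugs, diseases = NULL, adrs = NULL, targets = NULL) {
  drugs <- tibble::as_tibble(drugs)
  if (anyDuplicated(drugs$drug_id)) abort("duplicate drug_id")
  if (!"name" %in% names(drugs)) drugs$name <- drugs$drug_id
  if (!"smiles" %in% names(drugs)) drugs$smiles <- NA_character_
  if (!"atc" %in% names(drugs)) drugs$atc <- rep(list(character()), nrow(drugs))
  for (codes in drugs$atc) .check_atc(codes)
  empty <- function(col) tibble::tibble(drug_id = character(),
                                        !!col := character())
  diseases <- if (is.null(diseases)) empty("disease_id") else
    tibble::as_tibble(diseases)
  adrs <- if (is.null(adrs)) empty("adr_id") else tibble::as_tibble(adrs)
  targets <- if (is.null(targets)) {
    tibble::tibble(drug_id = character(), target_id = character(),
                   sign = double())
  } else {
    targets <- tibble::as_tibble(targets)
    if (!all(targets$sign %in% c(-1, 1))) abort("target signs must be +1 or -1")
    targets
  }
  for (tbl in list(diseases, adrs, targets)) {
    .check_known_drugs(tbl$drug_id, drugs$drug_id, "link table")
  }
  structure(list(drugs = drugs[c("drug_id", "name", "smiles", "atc")],
                 diseases = diseases, adrs = adrs, targets = targets),
            class = "drug_store")
}

.check_known_drugs <- function(ids, known, path) {
  unknown <- setdiff(ids, known)
  if (length(unknown) > 0) {
    abort(sprintf("%s refers to unknown drug_id '%s'", path, unknown[1]))
  }
}

.check_atc <- function(codes) {
  bad <- codes[!nchar(codes) %in% c(1L, 3L, 4L, 5L, 7L)]
  if (length(bad) > 0) {
    abort(sprintf("malformed ATC code '%s' (length must be 1, 3, 4, 5 or 7)",
                  bad[1]))
  }
  invisible(codes)
}

#' @export
print.drug_store <- function(x, ...) {
  cat(sprintf(
    "<drug_store> %d drugs | %d disease links | %d ADR links | %d target links\n",
    nrow(x$drugs), nrow(x$diseases), nrow(x$adrs), nrow(x$targets)))
  invisible(x)
}

.stopifnot_store <- function(store) {
  if (!inherits(store, "drug_store")) abort("expected a drug_store object")
}

.require_drug <- function(store, drug_id) {
  if (!drug_id %in% store$drugs$drug_id) {
    abort(sprintf("unknown drug_id '%s'", drug_id))
  }
  invisible(drug_id)
}

#' Extract one drug's annotation record from a store
#'
#' @param store A `drug_store`.
#' @param drug_id Drug identifier present in the store.
#' @return A list with elements `drug_id`, `name`, `smiles`, `atc`,
#'   `diseases`, `adrs` and `targets` (named numeric vector of +1/-1
#'   action signs, names are protein ids).
#' @export
drug_record <- function(store, drug_id) {
  .stopifnot_store(store)
  .require_drug(store, drug_id)
  row <- store$drugs[store$drugs$drug_id == drug_id, ]
  tg <- store$targets[store$targets$drug_id == drug_id, ]
  list(
    drug_id = drug_id,
    name = row$name,
    smiles = row$smiles,
    atc = row$atc[[1]],
    diseases = store$diseases$disease_id[store$diseases$drug_id == drug_id],
    adrs = store$adrs$adr_id[store$adrs$drug_id == drug_id],
    targets = setNames(tg$sign, tg$target_id)
  )
}

#' Read a signed directed protein interaction network
#'
#' Rows are `src`, `dst`, `sign` with sign in the accepted promotive /
#' inhibitory vocabulary (`+`, `-`, `+1`, `-1`, `activate`, `inhibit`, ...).
#' Self-loops are rejected; duplicate edges with conflicting signs are an
#' error naming the edge.
#'
#' @param path TSV file path.
#' @return A directed `igraph` with a `sign` edge attribute in {+1, -1}.
#' @export
read_signed_network <- function(path) {
  df <- .read_tsv(path, c("src", "dst", "sign"))
  df$sign <- .normalize_sign(df$sign, "sign", path)
  signed_network(df$src, df$dst, df$sign)
}

#' Build a signed directed network from vectors
#'
#' @param src,dst Character vectors of endpoint protein ids.
#' @param sign Numeric vector of +1/-1 edge signs.
#' @return A directed `igraph` with a `sign` edge attribute.
#' @export
signed_network <- function(src, dst, sign) {
  if (any(src == dst)) {
    abort(sprintf("self-loop on '%s' not allowed in a signed network",
                  src[src == dst][1]))
  }
  if (!all(sign %in% c(-1, 1))) abort("edge signs must be +1 or -1")
  key <- paste(src, dst, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first_sign <- sign[match(key, key)]
    if (any(sign != first_sign)) {
      i <- which(sign != first_sign)[1]
      abort(sprintf("conflicting signs for edge %s -> %s", src[i], dst[i]))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = src[!dup], to = dst[!dup], sign = sign[!dup]),
    directed = TRUE)
  g
}

#' Read an undirected protein-protein interaction network
#'
#' Rows are `protein_a`, `protein_b`. The graph is simplified: self-loops
#' are dropped with a warning and duplicate edges collapsed.
#'
#' @param path TSV file path.
#' @return An undirected simple `igraph`.
#' @export
read_ppi_network <- function(path) {
  df <- .read_tsv(path, c("protein_a", "protein_b"))
  loops <- df$protein_a == df$protein_b
  if (any(loops)) {
    warn(sprintf("%s: dropping %d self-loop(s)", path, sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g)
}

#' Read a GO biological-process DAG from an OBO file
#'
#' Parses `[Term]` stanzas, keeping `is_a` and `relationship: part_of`
#' edges (the two relations the Wang semantic-similarity measure weights).
#' Other relationship types are ignored with a warning; obsolete terms are
#' skipped. The result must be acyclic.
#'
#' @param path OBO file path.
#' @return A `go_dag` object: list with `terms` (character) and `edges`
#'   (tibble `child`, `parent`, `relation`).
#' @export
read_obo_dag <- function(path) {
  lines <- readLines(path)
  terms <- character(); edges <- list(); skipped <- character()
  in_term <- FALSE; cur_id <- NA_character_; obsolete <- FALSE
  stash <- list()
  commit <- function() {
    if (in_term && !is.na(cur_id) && !obsolete) {
      terms[[length(terms) + 1]] <<- cur_id
      for (e in stash) edges[[length(edges) + 1]] <<- e
    }
  }
  for (line in lines) {
    line <- trimws(sub("!.*$", "", line))
    if (line == "") next
    if (grepl("^\\[", line)) {
      commit()
      in_term <- line == "[Term]"
      cur_id <- NA_character_; obsolete <- FALSE; stash <- list()
    } else if (in_term) {
      if (grepl("^id:", line)) {
        cur_id <- trimws(sub("^id:", "", line))
      } else if (grepl("^is_obsolete:\\s*true", line)) {
        obsolete <- TRUE
      } else if (grepl("^is_a:", line)) {
        stash[[length(stash) + 1]] <- c(cur_id, trimws(sub("^is_a:", "", line)), "is_a")
      } else if (grepl("^relationship:", line)) {
        fields <- strsplit(trimws(sub("^relationship:", "", line)), "\\s+")[[1]]
        if (length(fields) >= 2 && fields[1] == "part_of") {
          stash[[length(stash) + 1]] <- c(cur_id, fields[2], "part_of")
        } else {
          skipped <- c(skipped, fields[1])
        }
      }
    }
  }
  commit()
  if (length(skipped) > 0) {
    warn(sprintf("%s: ignored relationship type(s): %s", path,
                 paste(unique(skipped), collapse = ", ")))
  }
  edges <- if (length(edges) == 0) {
    tibble::tibble(child = character(), parent = character(),
                   relation = character())
  } else {
    m <- do.call(rbind, edges)
    tibble::tibble(child = m[, 1], parent = m[, 2], relation = m[, 3])
  }
  go_dag(terms, edges)
}

#' Construct and validate a GO DAG
#'
#' @param terms Character vector of term ids.
#' @param edges Tibble/data frame with columns `child`, `parent`,
#'   `relation` (values `is_a` or `part_of`).
#' @return A `go_dag` object.
#' @export
go_dag <- function(terms, edges) {
  edges <- tibble::as_tibble(edges)
  terms <- unique(terms)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(unknown) > 0) {
    abort(sprintf("DAG edge endpoint '%s' is not a declared term", unknown[1]))
  }
  if (!all(edges$relation %in% c("is_a", "part_of"))) {
    abort("DAG edge relations must be 'is_a' or 'part_of'")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$child, to = edges$parent),
    directed = TRUE, vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) abort("cycle detected: term hierarchy is not a DAG")
  structure(list(terms = terms, edges = edges, graph = g,
                 cache = new.env(parent = emptyenv())),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges (%d is_a, %d part_of)\n",
              length(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "part_of")))
  invisible(x)
}

#' Read protein-to-GO-term annotations
#'
#' @param path TSV with columns `protein_id`, `go_term`.
#' @param dag Optional `go_dag`; when supplied, every annotated term must
#'   exist in the DAG.
#' @return Tibble with columns `protein_id`, `go_term`.
#' @export
read_annotations <- function(path, dag = NULL) {
  df <- dplyr::distinct(tibble::as_tibble(
    .read_tsv(path, c("protein_id", "go_term"))))
  if (!is.null(dag)) {
    unknown <- setdiff(df$go_term, dag$terms)
    if (length(unknown) > 0) {
      abort(sprintf("%s: annotation term '%s' absent from DAG", path,
                    unknown[1]))
    }
  }
  df
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: tab-separated `set_id`, `description`, genes...
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("%s line %d: GMT rows need at least 3 fields", path, i))
    }
    out[[fields[1]]] <- unique(trimws(fields[-(1:2)]))
  }
  out
}

#' Read a labeled drug-pair table
#'
#' Columns `drug_a`, `drug_b` and optional `label`
#' (`synergistic`/`antagonistic`; empty = unlabeled). Pairs are unordered:
#' each row is canonicalized so that `drug_a` sorts before `drug_b`.
#'
#' @param path TSV file path.
#' @return Tibble `drug_a`, `drug_b`, `label`.
#' @export
read_pairs <- function(path) {
  df <- .read_tsv(path, c("drug_a", "drug_b"), "label")
  if (!"label" %in% names(df)) df$label <- NA_character_
  df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  ok <- is.na(df$label) | df$label %in% c("synergistic", "antagonistic")
  if (!all(ok)) {
    abort(sprintf("%s: invalid label '%s' (expected synergistic/antagonistic)",
                  path, df$label[!ok][1]))
  }
  if (any(df$drug_a == df$drug_b)) {
    abort(sprintf("%s: pair of drug '%s' with itself", path,
                  df$drug_a[df$drug_a == df$drug_b][1]))
  }
  a <- pmin(df$drug_a, df$drug_b)
  b <- pmax(df$drug_a, df$drug_b)
  tibble::tibble(drug_a = a, drug_b = b, label = df$label)
}

#' Pair identifier shared by the CV record and interpretation layer
#'
#' @param drug_a,drug_b Drug id vectors; order does not matter.
#' @return Character vector `"<first>|<second>"` with ids in sorted order.
#' @export
pair_id <- function(drug_a, drug_b) {
  paste(pmin(drug_a, drug_b), pmax(drug_a, drug_b), sep = "|")
}

# ---- writers (round-trip counterparts of the readers) ----------------------

#' Write a drug store back to its four TSV tables
#'
#' @param store A `drug_store`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_drug_store <- function(store, dir) {
  .stopifnot_store(store)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("drugs.tsv", "drug_disease.tsv", "drug_adr.tsv",
                            "drug_target.tsv"))
  drugs <- store$drugs
  drugs$atc_codes <- vapply(drugs$atc, paste, "", collapse = "|")
  readr::write_tsv(drugs[c("drug_id", "name", "smiles", "atc_codes")],
                   paths[1], progress = FALSE)
  readr::write_tsv(store$diseases, paths[2], progress = FALSE)
  readr::write_tsv(store$adrs, paths[3], progress = FALSE)
  targets <- store$targets
  targets$action <- ifelse(targets$sign > 0, "activate", "inhibit")
  readr::write_tsv(targets[c("drug_id", "target_id", "action")], paths[4],
                   progress = FALSE)
  invisible(paths)
}

#' Write a signed directed network as TSV
#' @param graph Directed `igraph` with `sign` edge attribute.
#' @param path Output TSV path.
#' @export
write_signed_network <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  readr::write_tsv(
    tibble::tibble(src = el$from, dst = el$to,
                   sign = ifelse(el$sign > 0, "+", "-")),
    path, progress = FALSE)
  invisible(path)
}

#' Write an undirected PPI network as TSV
#' @param graph Undirected `igraph`.
#' @param path Output TSV path.
#' @export
write_ppi_network <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  readr::write_tsv(tibble::tibble(protein_a = el$from, protein_b = el$to),
                   path, progress = FALSE)
  invisible(path)
}

#' Write a GO DAG as a minimal OBO file
#' @param dag A `go_dag`.
#' @param path Output OBO path.
#' @export
write_obo_dag <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    e <- dag$edges[dag$edges$child == t, ]
    for (i in seq_len(nrow(e))) {
      if (e$relation[i] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[i]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[i]), con)
      }
    }
  }
  invisible(path)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output GMT path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a labeled pair table as TSV
#' @param pairs Tibble `drug_a`, `drug_b`, `label`.
#' @param path Output TSV path.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE, na = "")
  invisible(path)
}
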