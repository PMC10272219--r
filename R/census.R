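#' Construct a validated leaf census
#'
#' A leaf census holds one row per censused leaf (with its sampling hierarchy:
#' forest, depositional environment, quarry, and host plant taxon), a long
#' table of damage-type (DT) incidents on those leaves, and a DT catalog
#' mapping each DT code to a functional feeding group (FFG) and a
#' generalized/specialized class. Undamaged leaves are first-class citizens:
#' they appear in `leaves` with no rows in `damage`, so that damage
#' frequencies have the correct per-leaf-censused denominator.
#'
#' Duplicate `(leaf_id, dt_code)` damage rows are summed (incident-count
#' semantics); validation is idempotent.
#'
#' @param leaves data.frame with columns `leaf_id`, `forest`, `env`,
#'   `quarry`, `plant_taxon` (all character, non-empty); `leaf_id` unique.
#' @param damage data.frame with columns `leaf_id`, `dt_code`, `count`
#'   (positive integers), or `NULL` for a fully undamaged census.
#' @param catalog data.frame with columns `dt_code`, `ffg` (one of
#'   [ffg_levels()]), `spec_class` (`"generalized"` or `"specialized"`).
#' @return An object of class `leaf_census`: a list with elements `leaves`,
#'   `damage`, `catalog`, canonically ordered.
#' @export
leaf_census <- function(leaves, damage = NULL, catalog) {
  leaves <- as.data.frame(leaves, stringsAsFactors = FALSE)
  need <- c("leaf_id", "forest", "env", "quarry", "plant_taxon")
  if (!all(need %in% names(leaves))) {
    stop("`leaves` must have columns: ", paste(need, collapse = ", "))
  }
  leaves <- leaves[need]
  for (cl in need) leaves[[cl]] <- as.character(leaves[[cl]])
  if (nrow(leaves) == 0L) stop("census must contain at least one leaf")
  if (anyNA(leaves) || any(leaves == "")) {
    stop("leaf hierarchy fields must be non-empty and non-missing")
  }
  dup <- duplicated(leaves$leaf_id)
  if (any(dup)) {
    stop("duplicate leaf_id(s): ",
         paste(unique(leaves$leaf_id[dup]), collapse = ", "))
  }
  # a quarry id must resolve to a single (forest, env); a leaf_id to one taxon
  qmap <- unique(leaves[c("forest", "env", "quarry")])
  qdup <- qmap$quarry[duplicated(paste(qmap$forest, qmap$quarry, sep = "\r"))]
  if (length(qdup)) {
    stop("quarry id(s) reused across environments within a forest: ",
         paste(unique(qdup), collapse = ", "))
  }

  catalog <- validate_catalog(catalog)

  if (is.null(damage) || nrow(as.data.frame(damage)) == 0L) {
    damage <- data.frame(leaf_id = character(), dt_code = character(),
                         count = integer(), stringsAsFactors = FALSE)
  } else {
    damage <- as.data.frame(damage, stringsAsFactors = FALSE)
    if (!all(c("leaf_id", "dt_code", "count") %in% names(damage))) {
      stop("`damage` must have columns: leaf_id, dt_code, count")
    }
    damage <- damage[c("leaf_id", "dt_code", "count")]
    damage$leaf_id <- as.character(damage$leaf_id)
    damage$dt_code <- as.character(damage$dt_code)
    damage$count <- as.numeric(damage$count)
    if (anyNA(damage$count) || any(damage$count < 1) ||
        any(damage$count != round(damage$count))) {
      stop("damage counts must be positive integers (absence is encoded by ",
           "absence of the row, not by zero)")
    }
    damage$count <- as.integer(round(damage$count))
    unknown_leaf <- setdiff(damage$leaf_id, leaves$leaf_id)
    if (length(unknown_leaf)) {
      stop("damage rows reference unknown leaf_id(s): ",
           paste(head(unknown_leaf, 5L), collapse = ", "))
    }
    unknown_dt <- setdiff(damage$dt_code, catalog$dt_code)
    if (length(unknown_dt)) {
      stop("DT code(s) absent from catalog: ",
           paste(sort(unique(unknown_dt)), collapse = ", "))
    }
    # sum duplicate (leaf, DT) rows: incident counts accumulate
    key <- paste(damage$leaf_id, damage$dt_code, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- rowsum(damage$count, key)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      damage <- data.frame(
        leaf_id = vapply(parts, `[`, "", 1L),
        dt_code = vapply(parts, `[`, "", 2L),
        count = as.integer(agg[, 1L]),
        stringsAsFactors = FALSE
      )
    }
  }

  leaves <- leaves[order(leaves$forest, leaves$env, leaves$quarry,
                         leaves$leaf_id), , drop = FALSE]
  rownames(leaves) <- NULL
  damage <- damage[order(damage$leaf_id, damage$dt_code), , drop = FALSE]
  rownames(damage) <- NULL

  structure(list(leaves = leaves, damage = damage, catalog = catalog),
            class = "leaf_census")
}

validate_catalog <- function(catalog) {
  catalog <- as.data.frame(catalog, stringsAsFactors = FALSE)
  if (!all(c("dt_code", "ffg", "spec_class") %in% names(catalog))) {
    stop("catalog must have columns: dt_code, ffg, spec_class")
  }
  catalog <- catalog[c("dt_code", "ffg", "spec_class")]
  for (cl in names(catalog)) catalog[[cl]] <- as.character(catalog[[cl]])
  if (anyDuplicated(catalog$dt_code)) {
    stop("catalog contains duplicate dt_code entries")
  }
  bad_ffg <- setdiff(catalog$ffg, FFG_LEVELS)
  if (length(bad_ffg)) {
    stop("unknown FFG(s): ", paste(bad_ffg, collapse = ", "),
         "; must be one of: ", paste(FFG_LEVELS, collapse = ", "))
  }
  bad_sc <- setdiff(catalog$spec_class, SPEC_CLASS_LEVELS)
  if (length(bad_sc)) {
    stop("spec_class must be 'generalized' or 'specialized'; got: ",
         paste(bad_sc, collapse = ", "))
  }
  catalog <- catalog[order(catalog$dt_code), , drop = FALSE]
  rownames(catalog) <- NULL
  catalog
}

#' @export
print.leaf_census <- function(x, ...) {
  q <- unique(x$leaves[c("forest", "env", "quarry")])
  cat("<leaf_census>\n")
  cat("  leaves:   ", nrow(x$leaves), "\n", sep = "")
  cat("  forests:  ", length(unique(x$leaves$forest)), "\n", sep = "")
  cat("  quarries: ", nrow(q), "\n", sep = "")
  cat("  DTs seen: ", length(unique(x$damage$dt_code)),
      " of ", nrow(x$catalog), " in catalog\n", sep = "")
  invisible(x)
}

#' Number of leaves in a census
#' @param census A `leaf_census`.
#' @return Integer leaf count.
#' @export
leaf_count <- function(census) {
  stopifnot(inherits(census, "leaf_census"))
  nrow(census$leaves)
}

#' Per-quarry leaf tallies
#'
#' @param census A `leaf_census`.
#' @return data.frame with columns `forest`, `env`, `quarry`, `quarry_key`,
#'   `n_leaves`, one row per quarry.
#' @export
quarry_table <- function(census) {
  stopifnot(inherits(census, "leaf_census"))
  lv <- census$leaves
  key <- paste(lv$forest, lv$env, lv$quarry, sep = "/")
  tab <- table(key)
  first <- !duplicated(key)
  out <- data.frame(
    forest = lv$forest[first], env = lv$env[first], quarry = lv$quarry[first],
    quarry_key = key[first], stringsAsFactors = FALSE
  )
  out$n_leaves <- as.integer(tab[out$quarry_key])
  out <- out[order(out$quarry_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: census restricted to a set of leaf ids (catalog carried along).
subset_census <- function(census, leaf_ids) {
  leaf_census(
    leaves = census$leaves[census$leaves$leaf_id %in% leaf_ids, , drop = FALSE],
    damage = census$damage[census$damage$leaf_id %in% leaf_ids, , drop = FALSE],
    catalog = census$catalog
  )
}

#' Read a leaf census from long-format CSV files
#'
#' The census file is a UTF-8 CSV with header and columns exactly
#' `leaf_id, forest, depositional_environment, quarry, plant_taxon, dt_code,
#' count`. Damaged leaves have one row per (leaf, DT) incident record;
#' duplicate (leaf, DT) rows are summed. Undamaged leaves appear as a single
#' row with empty `dt_code` and `count`. The catalog file has columns
#' `dt_code, ffg, spec_class`.
#'
#' @param path Census CSV path.
#' @param catalog_path Catalog CSV path.
#' @return A validated [leaf_census()].
#' @export
read_census <- function(path, catalog_path) {
  if (!file.exists(path)) stop("census file not found: ", path)
  if (!file.exists(catalog_path)) stop("catalog file not found: ", catalog_path)
  raw <- read.csv(path, colClasses = "character", na.strings = character())
  need <- c("leaf_id", "forest", "depositional_environment", "quarry",
            "plant_taxon", "dt_code", "count")
  if (!identical(sort(names(raw)), sort(need))) {
    stop("census file must have columns exactly: ", paste(need, collapse = ", "))
  }
  cat_raw <- read.csv(catalog_path, colClasses = "character",
                      na.strings = character())

  leaf_rows <- raw[!duplicated(raw$leaf_id),
                   c("leaf_id", "forest", "depositional_environment",
                     "quarry", "plant_taxon")]
  names(leaf_rows) <- c("leaf_id", "forest", "env", "quarry", "plant_taxon")
  # conflicting hierarchy for a repeated leaf_id is a data error, not a merge
  hier <- paste(raw$leaf_id, raw$forest, raw$depositional_environment,
                raw$quarry, raw$plant_taxon, sep = "\r")
  n_hier <- tapply(hier, raw$leaf_id, function(h) length(unique(h)))
  if (any(n_hier > 1L)) {
    stop("leaf_id(s) with conflicting hierarchy/taxon: ",
         paste(names(n_hier)[n_hier > 1L], collapse = ", "))
  }

  dmg <- raw[raw$dt_code != "" | raw$count != "", c("leaf_id", "dt_code", "count")]
  if (nrow(dmg)) {
    if (any(dmg$dt_code == "")) stop("rows with a count but no dt_code")
    cnt <- suppressWarnings(as.numeric(dmg$count))
    if (anyNA(cnt)) stop("non-numeric damage count(s)")
    dmg$count <- cnt
  }
  leaf_census(leaves = leaf_rows, damage = dmg, catalog = cat_raw)
}

#' Write a leaf census to long-format CSV
#'
#' Inverse of [read_census()]: `read_census(write_census(x))` reproduces `x`.
#'
#' @param census A `leaf_census`.
#' @param path Output census CSV path.
#' @param catalog_path Optional output catalog CSV path.
#' @return Invisibly, `path`.
#' @export
write_census <- function(census, path, catalog_path = NULL) {
  stopifnot(inherits(census, "leaf_census"))
  lv <- census$leaves
  dm <- census$damage
  merged <- merge(dm, lv, by = "leaf_id", sort = FALSE)
  undamaged <- lv[!(lv$leaf_id %in% dm$leaf_id), , drop = FALSE]
  if (nrow(undamaged)) {
    undamaged$dt_code <- ""
    undamaged$count <- NA_integer_
    merged <- rbind(merged[names(undamaged)], undamaged)
  }
  out <- data.frame(
    leaf_id = merged$leaf_id, forest = merged$forest,
    depositional_environment = merged$env, quarry = merged$quarry,
    plant_taxon = merged$plant_taxon, dt_code = merged$dt_code,
    count = merged$count, stringsAsFactors = FALSE
  )
  out <- out[order(out$forest, out$depositional_environment, out$quarry,
                   out$leaf_id, out$dt_code), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(catalog_path)) {
    write.csv(census$catalog, catalog_path, row.names = FALSE)
  }
  invisible(path)
}

#' Drop quarries with too few leaves
#'
#' Quarries below the leaf-count threshold are removed so that rarefaction to
#' `min_leaves` and bootstrap resampling to the same size remain well defined.
#' The exclusion report preserves the identity and size of dropped quarries.
#'
#' @param census A `leaf_census`.
#' @param min_leaves Minimum leaves per retained quarry (default 300, the
#'   standardization size used throughout the package).
#' @return A list with `census` (the filtered census) and `excluded`
#'   (data.frame of removed quarries with their leaf counts).
#' @export
filter_quarries <- function(census, min_leaves = 300L) {
  stopifnot(inherits(census, "leaf_census"), min_leaves >= 1)
  qt <- quarry_table(census)
  drop <- qt[qt$n_leaves < min_leaves, , drop = FALSE]
  keep <- qt$quarry_key[qt$n_leaves >= min_leaves]
  if (!length(keep)) {
    stop("all quarries have fewer than ", min_leaves,
         " leaves; nothing left to analyse")
  }
  lv <- census$leaves
  key <- paste(lv$forest, lv$env, lv$quarry, sep = "/")
  kept <- subset_census(census, lv$leaf_id[key %in% keep])
  rownames(drop) <- NULL
  list(census = kept, excluded = drop)
}

#' Partition a census by hierarchy level
#'
#' Splits the census into views (each itself a valid `leaf_census`) by quarry,
#' depositional environment, or forest. The leaf multiset is preserved: every
#' leaf lands in exactly one view.
#'
#' @param census A `leaf_census`.
#' @param level One of `"quarry"`, `"env"`, `"forest"`.
#' @return Named list of `leaf_census` views; names are `forest`,
#'   `forest/env`, or `forest/env/quarry` keys.
#' @export
aggregate_census <- function(census, level = c("quarry", "env", "forest")) {
  stopifnot(inherits(census, "leaf_census"))
  level <- match.arg(level)
  lv <- census$leaves
  key <- switch(level,
    forest = lv$forest,
    env = paste(lv$forest, lv$env, sep = "/"),
    quarry = paste(lv$forest, lv$env, lv$quarry, sep = "/")
  )
  ids <- split(lv$leaf_id, key)
  lapply(ids, function(x) subset_census(census, x))
}
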