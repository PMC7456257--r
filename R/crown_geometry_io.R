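# Reading, writing and deriving sapling branch measurement tables.
#
# File dialect (CSV, UTF-8, header row), units as recorded in the field:
#   saplings.csv: sapling_id, strip_type, dbh_cm, ht_m, cl_m[, excluded_flag]
#   branches.csv: sapling_id, whorl_index, l_m, bl_cm, bc_cm, va_deg, bd_mm,
#                 azimuth_deg[, year_YYYY ...]
# Internally lengths are metres and angles radians.

.sapling_cols <- c("sapling_id", "strip_type", "dbh_cm", "ht_m", "cl_m")
.branch_cols  <- c("sapling_id", "whorl_index", "l_m", "bl_cm", "bc_cm",
                   "va_deg", "bd_mm", "azimuth_deg")
.strip_levels <- c("shelterwood_cut", "uncut")

#' Derive branch crown geometry
#'
#' Computes, per branch, the depth into the crown of the branch tip
#' (`DINC`, m), the outer crown radius (`OCR`, m) and the relative depth
#' (`RDINC = DINC / CL`):
#' \deqn{DINC = L - BC \cos(VA), \quad OCR = BC \sin(VA)}
#' where `L` is the distance from the sapling tip to the branch base (m),
#' `BC` the branch chord length (converted cm to m) and `VA` the branch
#' insertion angle (degrees, converted to radians). Branch angles above 90°
#' (observed in the field up to 160°) give a negative chord projection and
#' hence `DINC > L`; such branches may fall outside `RDINC` in `[0, 1]` and
#' are handled downstream by [validate_dataset()].
#'
#' @param l_m Tip-to-branch-base distance (m).
#' @param bc_cm Branch chord length (cm).
#' @param va_deg Branch angle (degrees, in (0, 180)).
#' @param cl_m Crown length of the parent sapling (m, > 0).
#' @return data.frame with columns `dinc_m`, `ocr_m`, `rdinc`.
#' @examples
#' derive_branch_geometry(1.0, 40, 90, 2.0)  # dinc 1.0, ocr 0.40, rdinc 0.5
#' @export
derive_branch_geometry <- function(l_m, bc_cm, va_deg, cl_m) {
  if (any(cl_m <= 0)) stop("crown length must be positive", call. = FALSE)
  va <- va_deg * pi / 180
  bc <- bc_cm / 100
  dinc <- l_m - bc * cos(va)
  ocr <- bc * sin(va)
  data.frame(dinc_m = dinc, ocr_m = ocr, rdinc = dinc / cl_m)
}

#' Crown ratio
#'
#' Crown length divided by total tree height, `CR = CL / HT`, dimensionless
#' in (0, 1].
#'
#' @param cl_m Crown length (m).
#' @param ht_m Total tree height (m, > 0).
#' @return Numeric vector of crown ratios.
#' @export
crown_ratio <- function(cl_m, ht_m) {
  if (any(ht_m <= 0)) stop("tree height must be positive", call. = FALSE)
  if (any(cl_m > ht_m + 1e-9)) {
    stop("crown length exceeds tree height", call. = FALSE)
  }
  cl_m / ht_m
}

#' Construct a crown dataset
#'
#' Bundles a sapling table and a branch table, checks referential integrity,
#' and computes derived geometry (`dinc_m`, `ocr_m`, `rdinc`, parent `cr`)
#' via [derive_branch_geometry()]. Saplings flagged in `excluded_flag`
#' (manual field-exclusion of biologically unreasonable profiles) are
#' removed together with their branches.
#'
#' @param saplings data.frame with columns `sapling_id`, `strip_type`
#'   (`"shelterwood_cut"` or `"uncut"`), `dbh_cm`, `ht_m`, `cl_m`, optional
#'   logical `excluded_flag`.
#' @param branches data.frame with columns `sapling_id`, `whorl_index`,
#'   `l_m`, `bl_cm`, `bc_cm`, `va_deg`, `bd_mm`, `azimuth_deg`, optional
#'   `year_YYYY` annual branch-length increment columns (cm).
#' @param provenance Free-text origin note.
#' @return An object of class `crown_dataset`: a list with elements
#'   `saplings`, `branches` (with derived columns) and `provenance`.
#' @export
crown_dataset <- function(saplings, branches, provenance = "") {
  saplings <- as.data.frame(saplings)
  branches <- as.data.frame(branches)
  miss_s <- setdiff(.sapling_cols, names(saplings))
  if (length(miss_s)) {
    stop("saplings table missing column(s): ", paste(miss_s, collapse = ", "),
         call. = FALSE)
  }
  miss_b <- setdiff(.branch_cols, names(branches))
  if (length(miss_b)) {
    stop("branches table missing column(s): ", paste(miss_b, collapse = ", "),
         call. = FALSE)
  }
  saplings$sapling_id <- as.character(saplings$sapling_id)
  branches$sapling_id <- as.character(branches$sapling_id)
  if (!all(saplings$strip_type %in% .strip_levels)) {
    stop("strip_type must be one of: ", paste(.strip_levels, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(saplings$sapling_id)) {
    stop("duplicate sapling_id in saplings table", call. = FALSE)
  }
  if ("excluded_flag" %in% names(saplings)) {
    keep <- !isTRUE_vec(saplings$excluded_flag)
    dropped <- saplings$sapling_id[!keep]
    saplings <- saplings[keep, , drop = FALSE]
    branches <- branches[!branches$sapling_id %in% dropped, , drop = FALSE]
  }
  unknown <- setdiff(branches$sapling_id, saplings$sapling_id)
  if (length(unknown)) {
    stop("branches reference unknown sapling_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  with_s <- nrow(saplings) > 0
  if (with_s) {
    bad_ht <- saplings$ht_m <= 1.3
    if (any(bad_ht)) {
      warning(sum(bad_ht), " sapling(s) below the 1.3 m height sampling criterion")
    }
    if (any(saplings$dbh_cm <= 0 | saplings$dbh_cm >= 5.0)) {
      warning("sapling DBH outside the (0, 5.0) cm sampling criterion")
    }
    if (any(saplings$cl_m <= 0 | saplings$cl_m > saplings$ht_m + 1e-9)) {
      stop("crown length must satisfy 0 < cl_m <= ht_m", call. = FALSE)
    }
  }
  if (nrow(branches) > 0) {
    idx <- match(branches$sapling_id, saplings$sapling_id)
    geom <- derive_branch_geometry(branches$l_m, branches$bc_cm,
                                   branches$va_deg, saplings$cl_m[idx])
    branches$dinc_m <- geom$dinc_m
    branches$ocr_m <- geom$ocr_m
    branches$rdinc <- geom$rdinc
    branches$cr <- crown_ratio(saplings$cl_m[idx], saplings$ht_m[idx])
    branches$dbh_cm <- saplings$dbh_cm[idx]
    if (any(branches$va_deg <= 0 | branches$va_deg >= 180)) {
      stop("branch angle va_deg must lie in (0, 180)", call. = FALSE)
    }
    if (any(branches$bc_cm <= 0 | branches$bc_cm > branches$bl_cm + 1e-9)) {
      stop("branch chord must satisfy 0 < bc_cm <= bl_cm", call. = FALSE)
    }
  } else {
    branches$dinc_m <- numeric(0); branches$ocr_m <- numeric(0)
    branches$rdinc <- numeric(0); branches$cr <- numeric(0)
    branches$dbh_cm <- numeric(0)
  }
  structure(list(saplings = saplings, branches = branches,
                 provenance = provenance),
            class = "crown_dataset")
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) x & !is.na(x)
  else x %in% c("TRUE", "true", "1", 1)
}

#' @export
print.crown_dataset <- function(x, ...) {
  cat("<crown_dataset>", nrow(x$saplings), "saplings,",
      nrow(x$branches), "branches\n")
  cnt <- dataset_counts(x)
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  %-16s %3d saplings, %4d branches\n",
                cnt$strip_type[i], cnt$n_saplings[i], cnt$n_branches[i]))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Per-strip sample sizes
#'
#' @param dataset A [crown_dataset].
#' @return data.frame with columns `strip_type`, `n_saplings`, `n_branches`.
#' @export
dataset_counts <- function(dataset) {
  stopifnot(inherits(dataset, "crown_dataset"))
  strips <- intersect(.strip_levels, unique(dataset$saplings$strip_type))
  out <- data.frame(strip_type = strips,
                    n_saplings = NA_integer_, n_branches = NA_integer_)
  for (i in seq_along(strips)) {
    ids <- dataset$saplings$sapling_id[dataset$saplings$strip_type == strips[i]]
    out$n_saplings[i] <- length(ids)
    out$n_branches[i] <- sum(dataset$branches$sapling_id %in% ids)
  }
  out
}

#' Subset a crown dataset to one strip
#'
#' @param dataset A [crown_dataset].
#' @param strip `"shelterwood_cut"` or `"uncut"`.
#' @return A [crown_dataset] restricted to saplings of that strip.
#' @export
filter_strip <- function(dataset, strip = .strip_levels) {
  stopifnot(inherits(dataset, "crown_dataset"))
  strip <- match.arg(strip)
  keep <- dataset$saplings$strip_type == strip
  ids <- dataset$saplings$sapling_id[keep]
  out <- dataset
  out$saplings <- dataset$saplings[keep, , drop = FALSE]
  out$branches <- dataset$branches[dataset$branches$sapling_id %in% ids, ,
                                   drop = FALSE]
  out
}

.read_numeric <- function(x, col, file) {
  suppress <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(suppress) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' of %s (row %d)",
                 x[bad[1]], col, file, bad[1]), call. = FALSE)
  }
  suppress
}

#' Read a sapling/branch measurement dataset from CSV
#'
#' Reads the two-file CSV dialect (see [crown_dataset()] for the schema),
#' optionally renaming columns via `schema`, derives branch geometry and
#' applies the relative-depth validation `policy`.
#'
#' @param saplings_path,branches_path Paths to the two CSV files.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the files, e.g. `c(dbh_cm = "DBH")`.
#' @param policy Passed to [validate_dataset()]; default `"clip"`.
#' @return A validated [crown_dataset]; the validation report is available
#'   via [validation_report()].
#' @export
read_branch_table <- function(saplings_path, branches_path, schema = NULL,
                              policy = c("clip", "drop", "fail")) {
  policy <- match.arg(policy)
  read_one <- function(path, mandatory) {
    if (!nzchar(path) || !file.exists(path)) {
      stop("measurement file not found: '", path, "'", call. = FALSE)
    }
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    if (!is.null(schema)) {
      for (canon in names(schema)) {
        if (schema[[canon]] %in% names(df)) {
          names(df)[names(df) == schema[[canon]]] <- canon
        }
      }
    }
    miss <- setdiff(mandatory, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing mandatory column(s): %s",
                   basename(path), paste(miss, collapse = ", ")), call. = FALSE)
    }
    num_cols <- setdiff(names(df), c("sapling_id", "strip_type", "excluded_flag"))
    for (col in num_cols) df[[col]] <- .read_numeric(df[[col]], col, basename(path))
    df
  }
  sap <- read_one(saplings_path, .sapling_cols)
  br <- read_one(branches_path, .branch_cols)
  if ("excluded_flag" %in% names(sap)) {
    sap$excluded_flag <- isTRUE_vec(sap$excluded_flag)
  }
  ds <- crown_dataset(sap, br,
                      provenance = paste0("read: ", saplings_path, " + ",
                                          branches_path))
  validate_dataset(ds, policy = policy)
}

#' Write a crown dataset to CSV
#'
#' Writes `saplings.csv` and `branches.csv` (raw measurement columns only,
#' field units) so that [read_branch_table()] round-trips the dataset.
#'
#' @param dataset A [crown_dataset].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_branch_table <- function(dataset, dir) {
  stopifnot(inherits(dataset, "crown_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "saplings.csv")
  bp <- file.path(dir, "branches.csv")
  year_cols <- grep("^year_", names(dataset$branches), value = TRUE)
  br <- dataset$branches[, c(.branch_cols, year_cols), drop = FALSE]
  sap_cols <- intersect(c(.sapling_cols, "excluded_flag"),
                        names(dataset$saplings))
  utils::write.csv(dataset$saplings[, sap_cols, drop = FALSE], sp,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(br, bp, row.names = FALSE, quote = FALSE)
  invisible(c(saplings = sp, branches = bp))
}

#' Keep the largest branch of each whorl
#'
#' For candidate-model comparison the study fits on the branch with the
#' largest radius from each whorl. Selection is by maximal outer crown
#' radius (`by = "ocr"`, the modelled quantity) or maximal branch diameter
#' (`by = "bd"`); ties are broken by larger branch diameter, then by table
#' order (deterministic).
#'
#' @param dataset A [crown_dataset] with derived geometry.
#' @param by `"ocr"` (default) or `"bd"`.
#' @return A [crown_dataset] with exactly one branch per (sapling, whorl).
#' @export
largest_branch_per_whorl <- function(dataset, by = c("ocr", "bd")) {
  stopifnot(inherits(dataset, "crown_dataset"))
  by <- match.arg(by)
  br <- dataset$branches
  if (nrow(br) == 0) return(dataset)
  key <- paste(br$sapling_id, br$whorl_index, sep = "\r")
  primary <- if (by == "ocr") br$ocr_m else br$bd_mm
  ord <- order(key, -primary, -br$bd_mm, seq_len(nrow(br)))
  first <- !duplicated(key[ord])
  out <- dataset
  out$branches <- br[sort(ord[first]), , drop = FALSE]
  rownames(out$branches) <- NULL
  out
}

#' Validate derived branch geometry
#'
#' Applies the relative-depth rule: branches must have `rdinc` in `[0, 1]`.
#' Violations (possible for branch angles above 90°, where the chord
#' projection is negative) are handled per `policy`:
#' `"clip"` snaps `rdinc` to the nearest bound and recomputes `dinc_m`
#' (retains the full sample, the default), `"drop"` removes the branch,
#' `"fail"` raises an error. A unit-consistency rule additionally flags
#' branches whose outer radius exceeds the branch length (`ocr_m >
#' bl_cm/100`), which indicates a cm/m confusion upstream; these are
#' reported, never altered.
#'
#' @param dataset A [crown_dataset].
#' @param policy `"clip"`, `"drop"` or `"fail"`.
#' @return The dataset with the policy applied; the report data.frame
#'   (columns `rule`, `sapling_id`, `whorl_index`, `value`) is attached as
#'   attribute `"validation_report"` (see [validation_report()]).
#' @export
validate_dataset <- function(dataset, policy = c("clip", "drop", "fail")) {
  stopifnot(inherits(dataset, "crown_dataset"))
  policy <- match.arg(policy)
  br <- dataset$branches
  report <- data.frame(rule = character(0), sapling_id = character(0),
                       whorl_index = integer(0), value = numeric(0))
  add <- function(rule, rows, value) {
    if (!length(rows)) return()
    report <<- rbind(report, data.frame(
      rule = rule, sapling_id = br$sapling_id[rows],
      whorl_index = br$whorl_index[rows], value = value))
  }
  if (nrow(br) > 0) {
    low <- which(br$rdinc < 0)
    high <- which(br$rdinc > 1)
    add("rdinc_below_0", low, br$rdinc[low])
    add("rdinc_above_1", high, br$rdinc[high])
    unit <- which(br$ocr_m > br$bl_cm / 100 + 1e-9)
    add("ocr_exceeds_bl", unit, br$ocr_m[unit])
    viol <- c(low, high)
    if (length(viol)) {
      if (policy == "fail") {
        stop(length(viol), " branch(es) violate rdinc in [0, 1]", call. = FALSE)
      } else if (policy == "drop") {
        br <- br[-viol, , drop = FALSE]
      } else {
        idx <- match(br$sapling_id, dataset$saplings$sapling_id)
        cl <- dataset$saplings$cl_m[idx]
        br$rdinc[low] <- 0
        br$rdinc[high] <- 1
        br$dinc_m[viol] <- br$rdinc[viol] * cl[viol]
      }
    }
  }
  out <- dataset
  out$branches <- br
  rownames(out$branches) <- NULL
  attr(out, "validation_report") <- report
  out
}

#' Retrieve the validation report of a dataset
#'
#' @param dataset A [crown_dataset] returned by [validate_dataset()] or
#'   [read_branch_table()].
#' @return The report data.frame (empty if the dataset was clean or not yet
#'   validated).
#' @export
validation_report <- function(dataset) {
  rep <- attr(dataset, "validation_report")
  if (is.null(rep)) {
    rep <- data.frame(rule = character(0), sapling_id = character(0),
                      whorl_index = integer(0), value = numeric(0))
  }
  rep
}
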