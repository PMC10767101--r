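#' Raw specimen landmark container
#'
#' Bundles one tooth's digitised landmark sets: ordered fixed cusp points
#' ("EDJ main"), ordered EDJ marginal-ridge curve samples ("EDJ ridge") and
#' ordered cervical curve samples ("CEJ ridge"), with specimen metadata.
#' Raw curves are ordered but not equidistant; counts are free (>= 4 per
#' curve), only the derived homologous configuration has fixed counts.
#'
#' @param specimen_id Specimen identifier.
#' @param tooth A [tooth_class()].
#' @param fixed_points Numeric matrix (n_fixed x 3, mm) of cusp apices, or a
#'   0-row matrix for anterior teeth.
#' @param edj_ridge_points Numeric matrix (m x 3) of ordered ridge samples
#'   (0-row for anterior teeth).
#' @param cej_points Numeric matrix (m x 3) of ordered cervix samples.
#' @param taxon,group,side Metadata; `side` is `"left"` or `"right"`.
#' @return Object of class `raw_specimen`.
#' @export
raw_specimen <- function(specimen_id, tooth, fixed_points, edj_ridge_points,
                         cej_points, taxon = NA_character_,
                         group = NA_character_, side = "right") {
  stopifnot(inherits(tooth, "tooth_class"))
  fixed_points <- as_coord_matrix(fixed_points, "fixed_points")
  edj_ridge_points <- as_coord_matrix(edj_ridge_points, "edj_ridge_points")
  cej_points <- as_coord_matrix(cej_points, "cej_points")
  if (is.na(side) || !nzchar(side)) {
    warning("specimen ", specimen_id, ": missing side metadata, defaulting to right")
    side <- "right"
  }
  side <- match.arg(side, c("left", "right"))
  layout <- landmark_layout(tooth)
  if (nrow(fixed_points) != layout$n_fixed) {
    stop("fixed-point count mismatch: expected ", layout$n_fixed,
         " for ", tooth$position_label, ", got ", nrow(fixed_points))
  }
  if (layout$n_fixed > 0) check_curve_points(edj_ridge_points, "EDJ ridge")
  check_curve_points(cej_points, "CEJ")
  structure(
    list(
      specimen_id = specimen_id, taxon = taxon, group = group,
      tooth = tooth, side = side,
      fixed_points = fixed_points,
      edj_ridge_points = edj_ridge_points,
      cej_points = cej_points
    ),
    class = "raw_specimen"
  )
}

as_coord_matrix <- function(x, what) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0) {
    return(matrix(numeric(0), 0, 3))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, ": expected 3 columns, got ", ncol(x))
  if (any(!is.finite(x))) stop(what, ": non-finite coordinate")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

check_curve_points <- function(pts, what) {
  if (nrow(pts) < 4) stop(what, " curve: need >= 4 points, got ", nrow(pts))
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d < 1e-12)) stop(what, " curve: consecutive duplicate points")
  invisible(TRUE)
}

#' @export
print.raw_specimen <- function(x, ...) {
  cat(sprintf(
    "<raw_specimen> %s [%s %s, %s] fixed:%d ridge:%d cej:%d\n",
    x$specimen_id, x$tooth$arcade, x$tooth$position_label, x$side,
    nrow(x$fixed_points), nrow(x$edj_ridge_points), nrow(x$cej_points)
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Landmark file formats.
#
# TPS dialect: one LM3=<n> block per landmark set in fixed order (EDJ main,
# EDJ ridge, CEJ ridge; anterior teeth write the first two blocks with n=0),
# one "x y z" triple per line (6 decimals), then ID=<specimen_id>.
#
# CSV dialect: columns set,index,x,y,z with set in {fixed, ridge, cej}.
# ---------------------------------------------------------------------------

#' Write a raw specimen landmark file
#'
#' @param spec A [raw_specimen()].
#' @param path Output path.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_landmark_file()]
#' @export
write_landmark_file <- function(spec, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  sets <- list(fixed = spec$fixed_points, ridge = spec$edj_ridge_points,
               cej = spec$cej_points)
  if (format == "tps") {
    lines <- character(0)
    for (nm in names(sets)) {
      m <- sets[[nm]]
      lines <- c(lines, sprintf("LM3=%d", nrow(m)))
      if (nrow(m) > 0) {
        lines <- c(lines, apply(m, 1, function(p) {
          paste(sprintf("%.6f", p), collapse = " ")
        }))
      }
    }
    lines <- c(lines, sprintf("ID=%s", spec$specimen_id))
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, lapply(names(sets), function(nm) {
      m <- sets[[nm]]
      if (nrow(m) == 0) return(NULL)
      data.frame(set = nm, index = seq_len(nrow(m)),
                 x = sprintf("%.6f", m[, 1]), y = sprintf("%.6f", m[, 2]),
                 z = sprintf("%.6f", m[, 3]))
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a raw specimen landmark file
#'
#' Reads either dialect written by [write_landmark_file()] and validates the
#' point counts against the expected layout. Coordinates are returned as
#' stored (mm, 6 decimals in files).
#'
#' @param path File path.
#' @param tooth The [tooth_class()] the file is expected to contain.
#' @param format `"auto"` (by extension), `"tps"` or `"csv"`.
#' @param ... Metadata passed to [raw_specimen()] (`taxon`, `group`, `side`).
#' @return A [raw_specimen()].
#' @export
read_landmark_file <- function(path, tooth, format = c("auto", "tps", "csv"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tps"
  }
  if (format == "tps") {
    lines <- readLines(path)
    sets <- list(); id <- NULL; i <- 1; set_i <- 0
    set_names <- c("fixed", "ridge", "cej")
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1; next }
      if (grepl("^LM3=", ln)) {
        n <- suppressWarnings(as.integer(sub("^LM3=", "", ln)))
        if (is.na(n)) stop("malformed LM3 header at line ", i, " of ", path)
        set_i <- set_i + 1
        if (set_i > 3) stop("too many LM3 blocks at line ", i, " of ", path)
        pts <- matrix(numeric(0), 0, 3)
        if (n > 0) {
          if (i + n > length(lines)) stop("truncated block at line ", i, " of ", path)
          vals <- lapply(seq_len(n), function(j) {
            v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]), "\\s+")[[1]]))
            if (length(v) != 3 || any(!is.finite(v))) {
              stop("malformed coordinate at line ", i + j, " of ", path)
            }
            v
          })
          pts <- do.call(rbind, vals)
        }
        sets[[set_names[set_i]]] <- pts
        i <- i + n + 1
      } else if (grepl("^ID=", ln)) {
        id <- sub("^ID=", "", ln)
        i <- i + 1
      } else {
        stop("unexpected content at line ", i, " of ", path)
      }
    }
    if (set_i != 3) stop("expected 3 LM3 blocks in ", path, ", found ", set_i)
    if (is.null(id)) id <- basename(path)
    raw_specimen(id, tooth, sets$fixed, sets$ridge, sets$cej, ...)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("set", "index", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("CSV landmark file ", path, " missing columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
      bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))[1]
      stop("non-finite coordinate at row ", bad, " of ", path)
    }
    get_set <- function(nm) {
      sub <- df[df$set == nm, , drop = FALSE]
      sub <- sub[order(sub$index), , drop = FALSE]
      as.matrix(sub[, c("x", "y", "z")])
    }
    raw_specimen(basename_noext(path), tooth, get_set("fixed"), get_set("ridge"),
                 get_set("cej"), ...)
  }
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Mirror a left-sided specimen to the right-side convention
#'
#' Analyses pool antimeres by presenting every tooth as right-sided. Left
#' specimens are reflected across the first coordinate axis (x negated) and
#' each curve's ring ordering is reversed (keeping its start point first) so
#' that the digitising direction convention ("continuing mesially" from the
#' stated start) still holds after reflection. Right specimens are returned
#' unchanged. The operation is an involution and preserves centroid size and
#' all inter-landmark distances.
#'
#' @param spec A [raw_specimen()].
#' @return A [raw_specimen()] in right-side convention.
#' @export
mirror_to_right <- function(spec) {
  stopifnot(inherits(spec, "raw_specimen"))
  if (spec$side == "right") return(spec)
  refl <- function(m) { if (nrow(m)) m[, 1] <- -m[, 1]; m }
  rev_ring <- function(m) {
    if (nrow(m) < 2) return(m)
    m[c(1, nrow(m):2), , drop = FALSE]
  }
  out <- spec
  out$side <- "right"
  out$fixed_points <- refl(spec$fixed_points)
  out$edj_ridge_points <- rev_ring(refl(spec$edj_ridge_points))
  out$cej_points <- rev_ring(refl(spec$cej_points))
  out
}

# ---------------------------------------------------------------------------
# Manifest
# ---------------------------------------------------------------------------

#' Load a specimen manifest
#'
#' The manifest CSV has columns `specimen_id, taxon, group, tooth, arcade,
#' side, path` with one row per tooth. `group` is the analysis pooling label.
#' `(specimen_id, tooth, arcade)` must be unique and every referenced file
#' must exist (relative paths resolve against the manifest's directory).
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every landmark file exists (default TRUE).
#' @return A `data.frame` of class `edj_manifest` with a `path` column of
#'   resolved file paths.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "taxon", "group", "tooth", "arcade", "side", "path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$specimen_id, df$tooth, df$arcade)
  if (anyDuplicated(key)) {
    stop("duplicate specimen/tooth row(s) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  root <- dirname(normalizePath(path))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                     file.path(root, df$path))
  if (check_files) {
    missing <- resolved[!file.exists(resolved)]
    if (length(missing)) {
      stop("manifest references missing file(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  df$path <- resolved
  class(df) <- c("edj_manifest", "data.frame")
  df
}

#' Write a specimen manifest
#' @param manifest Data frame with the manifest columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read every specimen referenced by a manifest
#'
#' Reads each landmark file, attaches metadata, and mirrors left-sided
#' specimens to the right-side convention.
#'
#' @param manifest An `edj_manifest` from [load_manifest()].
#' @param mirror Mirror left specimens to right (default TRUE).
#' @return List of [raw_specimen()] objects.
#' @export
read_manifest_specimens <- function(manifest, mirror = TRUE) {
  specs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    tooth <- tooth_class(row$tooth, row$arcade)
    sp <- read_landmark_file(row$path, tooth, taxon = row$taxon,
                             group = row$group, side = row$side)
    sp$specimen_id <- row$specimen_id
    if (mirror) sp <- mirror_to_right(sp)
    sp
  })
  names(specs) <- paste(manifest$specimen_id, manifest$tooth, sep = "_")
  specs
}
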