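#' Construct a PlateLayout
#'
#' @param roles character matrix of per-cell roles (`"control"`, `"standard"`,
#'   `"sample"`, `"empty"`).
#' @param conc numeric matrix of standard concentrations in mM; ignored except
#'   for standard cells. Controls are fixed at 0 mM.
#' @param labels optional character matrix of well labels.
#' @return A [PlateLayout-class].
#' @examples
#' layout <- defaultLayout()
#' nonEmptyCells(layout)
#' @export
PlateLayout <- function(roles, conc = NULL, labels = NULL) {
  nr <- nrow(roles); nc <- ncol(roles)
  if (is.null(conc)) conc <- matrix(NA_real_, nr, nc)
  if (is.null(labels)) labels <- matrix("", nr, nc)
  conc[roles == "control"] <- 0
  conc[!roles %in% c("control", "standard")] <- NA_real_
  new("PlateLayout", nRows = as.integer(nr), nCols = as.integer(nc),
      roles = roles, conc = conc, labels = labels)
}

#' @rdname PlateLayout
#' @param x,object a `PlateLayout`.
#' @export
setGeneric("nonEmptyCells", function(x) standardGeneric("nonEmptyCells"))

#' Enumerate the non-empty wells of a layout
#'
#' @return A data.frame with columns `grid_row`, `grid_col` (0-based),
#'   `role`, `conc_mM` (`NA` for samples), `label`, in row-major grid order.
#' @rdname PlateLayout
#' @export
setMethod("nonEmptyCells", "PlateLayout", function(x) {
  idx <- which(t(x@roles) != "empty")  # row-major order
  gc <- (idx - 1L) %% x@nCols
  gr <- (idx - 1L) %/% x@nCols
  data.frame(grid_row = gr, grid_col = gc,
             role = x@roles[cbind(gr + 1L, gc + 1L)],
             conc_mM = x@conc[cbind(gr + 1L, gc + 1L)],
             label = x@labels[cbind(gr + 1L, gc + 1L)],
             stringsAsFactors = FALSE)
})

#' @rdname PlateLayout
#' @export
setMethod("show", "PlateLayout", function(object) {
  cells <- nonEmptyCells(object)
  cat(sprintf("PlateLayout: %d x %d grid, %d wells (%d calibration, %d sample)\n",
              object@nRows, object@nCols, nrow(cells),
              sum(cells$role %in% c("control", "standard")),
              sum(cells$role == "sample")))
})

#' The shipped default plate layout
#'
#' Two rows mirroring the assay's bench convention: the top row holds the
#' water control (0 mM) followed by the eight cadmium sulfate standards at
#' 0.1, 0.25, 0.5, 0.6, 0.8, 1.0, 1.5 and 2 mM; the bottom row holds the
#' unknown samples, left-aligned.
#'
#' @param sample_labels character vector of sample labels (default S1..S3).
#' @return A [PlateLayout-class] with 2 rows and 9 columns.
#' @export
defaultLayout <- function(sample_labels = c("S1", "S2", "S3")) {
  standards <- c(0.1, 0.25, 0.5, 0.6, 0.8, 1.0, 1.5, 2.0)
  ns <- length(sample_labels)
  if (ns > 9L)
    clStop("cadmilume_config_error", "at most 9 samples fit the default layout")
  roles <- matrix("empty", 2, 9)
  conc <- matrix(NA_real_, 2, 9)
  labels <- matrix("", 2, 9)
  roles[1, 1] <- "control"
  roles[1, 2:9] <- "standard"
  conc[1, 2:9] <- standards
  if (ns > 0) {
    roles[2, seq_len(ns)] <- "sample"
    labels[2, seq_len(ns)] <- sample_labels
  }
  PlateLayout(roles, conc, labels)
}

#' Read a plate layout from a JSON configuration
#'
#' The configuration declares the grid size and each well's role:
#' \preformatted{
#' {"n_rows": 2, "n_cols": 9,
#'  "wells": [{"row": 0, "col": 0, "role": "control"},
#'            {"row": 0, "col": 1, "role": "standard", "conc_mM": 0.1},
#'            {"row": 1, "col": 0, "role": "sample", "label": "S1"}]}
#' }
#' Rows and columns are 0-based. Cells not listed are empty. Unknown roles,
#' standards without a concentration, and duplicate cells are configuration
#' errors naming the offending cell.
#'
#' @param config path to a JSON file, a JSON string, or an equivalent list.
#' @return A [PlateLayout-class].
#' @export
parseLayout <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  nr <- as.integer(config$n_rows %||% clStop("cadmilume_config_error", "n_rows missing"))
  nc <- as.integer(config$n_cols %||% clStop("cadmilume_config_error", "n_cols missing"))
  roles <- matrix("empty", nr, nc)
  conc <- matrix(NA_real_, nr, nc)
  labels <- matrix("", nr, nc)
  seen <- matrix(FALSE, nr, nc)
  for (w in config$wells) {
    r <- as.integer(w$row); c <- as.integer(w$col)
    cell <- sprintf("(row %d, col %d)", r, c)
    if (is.na(r) || is.na(c) || r < 0 || r >= nr || c < 0 || c >= nc)
      clStop("cadmilume_config_error", sprintf("well %s outside the grid", cell))
    if (seen[r + 1, c + 1])
      clStop("cadmilume_config_error", sprintf("duplicate well %s", cell))
    seen[r + 1, c + 1] <- TRUE
    role <- w$role %||% ""
    if (!role %in% c("control", "standard", "sample", "empty"))
      clStop("cadmilume_config_error",
             sprintf("unknown role '%s' at well %s", role, cell))
    if (role == "standard") {
      cc <- suppressWarnings(as.numeric(w$conc_mM %||% NA))
      if (!is.finite(cc) || cc < 0)
        clStop("cadmilume_config_error",
               sprintf("standard well %s needs a finite conc_mM >= 0", cell))
      conc[r + 1, c + 1] <- cc
    }
    roles[r + 1, c + 1] <- role
    labels[r + 1, c + 1] <- as.character(w$label %||% "")
  }
  PlateLayout(roles, conc, labels)
}

#' Serialize a plate layout to JSON
#'
#' `parseLayout(serializeLayout(layout))` reproduces the layout.
#'
#' @param layout a [PlateLayout-class].
#' @param path optional output file; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
serializeLayout <- function(layout, path = NULL) {
  cells <- nonEmptyCells(layout)
  wells <- lapply(seq_len(nrow(cells)), function(i) {
    w <- list(row = cells$grid_row[i], col = cells$grid_col[i],
              role = cells$role[i])
    if (cells$role[i] == "standard") w$conc_mM <- cells$conc_mM[i]
    if (nzchar(cells$label[i])) w$label <- cells$label[i]
    w
  })
  js <- jsonlite::toJSON(list(n_rows = layout@nRows, n_cols = layout@nCols,
                              wells = wells),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
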