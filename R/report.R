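# Threshold-based QC flagging of image-derived phenotypes and a standalone
# single-file HTML report (tables plus matrix/distribution panels, all images
# embedded base64 so the page opens with no network or source-file access).

#' Threshold specification for IDP pass/fail evaluation
#'
#' Inclusive pass range per IDP; an absent bound is unbounded. Threshold
#' values are dataset-specific and deliberately ship without defaults.
#'
#' @param idp character vector of IDP names.
#' @param lower,upper numeric bounds (`NA` = unbounded on that side).
#' @return `data.frame` of class `threshold_spec`.
#' @export
threshold_spec <- function(idp, lower = NA_real_, upper = NA_real_) {
  idp <- as.character(idp)
  lower <- rep_len(as.numeric(lower), length(idp))
  upper <- rep_len(as.numeric(upper), length(idp))
  if (anyDuplicated(idp)) stop("IDP names in the spec must be unique")
  bad <- !is.na(lower) & !is.na(upper) & lower > upper
  if (any(bad))
    stop("lower > upper for: ", paste(idp[bad], collapse = ", "))
  structure(data.frame(idp = idp, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("threshold_spec", "data.frame"))
}

#' Read a threshold specification from TSV
#'
#' Expected columns `idp`, `lower`, `upper` (tab-separated, empty cells for
#' absent bounds).
#'
#' @param path TSV path.
#' @return A [threshold_spec()].
#' @export
read_threshold_spec <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric"))
  need <- c("idp", "lower", "upper")
  if (!all(need %in% names(df)))
    stop("threshold spec must have columns: ", paste(need, collapse = ", "))
  threshold_spec(df$idp, df$lower, df$upper)
}

#' Evaluate IDP values against pass/fail thresholds
#'
#' An IDP passes iff lower <= value <= upper (inclusive; absent bounds are
#' unbounded). Missing values get status `missing`; IDPs without an entry in
#' the spec get `no-threshold`.
#'
#' @param values named numeric vector (or single-row data frame) of IDP
#'   values.
#' @param spec a [threshold_spec()].
#' @param subject optional subject identifier carried into the record.
#' @return `data.frame` of class `qc_record`: `subject`, `idp`, `value`,
#'   `status` in \{pass, fail, missing, no-threshold\}.
#' @export
evaluate_thresholds <- function(values, spec, subject = NA_character_) {
  if (is.data.frame(values)) values <- unlist(values[1L, , drop = TRUE])
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be named by IDP")
  if (!is.numeric(values))
    stop("non-numeric IDP value(s): ",
         paste(names(values)[!vapply(values, is.numeric, TRUE)],
               collapse = ", "))
  status <- character(length(values))
  for (i in seq_along(values)) {
    row <- match(names(values)[i], spec$idp)
    if (is.na(row)) { status[i] <- "no-threshold"; next }
    v <- values[[i]]
    if (is.na(v)) { status[i] <- "missing"; next }
    lo <- spec$lower[row]; hi <- spec$upper[row]
    ok <- (is.na(lo) || v >= lo) && (is.na(hi) || v <= hi)
    status[i] <- if (ok) "pass" else "fail"
  }
  structure(data.frame(subject = subject, idp = names(values),
                       value = as.numeric(values), status = status,
                       stringsAsFactors = FALSE),
            class = c("qc_record", "data.frame"))
}

# render a plot closure to a base64 <img> tag
panel_img <- function(draw, width = 560, height = 420, title = NULL) {
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path))
  grDevices::png(path, width = width, height = height, res = 96,
                 type = "cairo")
  ok <- tryCatch({ draw(); TRUE },
                 error = function(e) { graphics::plot.new(); FALSE })
  grDevices::dev.off()
  uri <- base64enc::dataURI(file = path, mime = "image/png")
  cap <- if (is.null(title)) "" else sprintf("<h3>%s</h3>\n", title)
  sprintf("<div class='panel'>%s<img alt='%s' src='%s'/></div>",
          cap, if (is.null(title)) "panel" else title, uri)
}

placeholder_panel <- function(title, msg = "no data") {
  sprintf("<div class='panel'><h3>%s</h3><p class='nodata'>%s</p></div>",
          title, msg)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

qc_table_html <- function(qc) {
  rows <- vapply(seq_len(nrow(qc)), function(i) {
    cls <- switch(qc$status[i], pass = "pass", fail = "fail",
                  missing = "missing", "nothr")
    val <- if (is.na(qc$value[i])) "" else signif(qc$value[i], 6)
    sprintf("<tr class='%s'><td>%s</td><td>%s</td><td>%s</td></tr>",
            cls, html_escape(qc$idp[i]), val, qc$status[i])
  }, character(1))
  paste0("<table class='idp'><tr><th>IDP</th><th>value</th>",
         "<th>status</th></tr>\n", paste(rows, collapse = "\n"), "</table>")
}

heat_colors <- function(n = 64) grDevices::hcl.colors(n, "RdBu", rev = TRUE)

#' Render a standalone HTML QC report for one subject
#'
#' Produces a single self-contained HTML file: the color-coded IDP pass/fail
#' table plus, when the corresponding inputs are given, an FC heatmap, FC
#' histogram, log-scaled SC weights heatmap, SC weight histogram, ROI
#' time-series carpet plot and framewise-displacement trace. All images are
#' embedded as base64 PNG, so the file opens offline with no references to
#' the subject's source data.
#'
#' @param qc a `qc_record` from [evaluate_thresholds()].
#' @param path output `.html` path.
#' @param fc optional `fc_matrix`.
#' @param conn optional [connectome()].
#' @param ts optional `roi_timeseries`.
#' @param motion optional T x 6 motion-parameter matrix.
#' @param subject subject label shown in the page header.
#' @return `path`, invisibly.
#' @export
render_report <- function(qc, path, fc = NULL, conn = NULL, ts = NULL,
                          motion = NULL, subject = "subject") {
  panels <- character(0)

  if (!is.null(fc)) {
    v <- fc$values
    finite <- v[upper.tri(v)][is.finite(v[upper.tri(v)])]
    if (length(finite)) {
      panels <- c(panels,
        panel_img(function() {
          vv <- v; vv[!is.finite(vv)] <- 0
          graphics::image(seq_len(nrow(vv)), seq_len(ncol(vv)),
                          vv[, rev(seq_len(ncol(vv)))], zlim = c(-1, 1),
                          col = heat_colors(), xlab = "ROI", ylab = "ROI",
                          main = "Functional connectivity (Pearson r)")
        }, title = "FC matrix"),
        panel_img(function()
          graphics::hist(finite, breaks = 30, col = "grey70",
                         xlab = "Pearson r", main = "FC distribution"),
          title = "FC histogram"))
    } else {
      panels <- c(panels, placeholder_panel("FC matrix"),
                  placeholder_panel("FC histogram"))
    }
  }

  if (!is.null(conn)) {
    w <- conn$weights
    nz <- w[w > 0]
    if (length(nz)) {
      eps <- min(nz) / 10   # log display floor for zero weights
      panels <- c(panels,
        panel_img(function()
          graphics::image(seq_len(nrow(w)), seq_len(ncol(w)),
                          log10(w + eps)[, rev(seq_len(ncol(w)))],
                          col = grDevices::hcl.colors(64, "Viridis"),
                          xlab = "ROI", ylab = "ROI",
                          main = "SC weights, log10 scale"),
          title = "SC weights"),
        panel_img(function()
          graphics::hist(log10(nz), breaks = 30, col = "grey70",
                         xlab = "log10(weight)",
                         main = "Nonzero SC weight distribution"),
          title = "SC histogram"))
    } else {
      panels <- c(panels,
                  placeholder_panel("SC weights", "empty connectome"),
                  placeholder_panel("SC histogram", "empty connectome"))
    }
  }

  if (!is.null(ts)) {
    V <- ts$values[, ts$valid, drop = FALSE]
    if (ncol(V) >= 1L) {
      panels <- c(panels, panel_img(function() {
        Z <- scale(V)
        graphics::image(seq_len(nrow(Z)), seq_len(ncol(Z)), Z,
                        col = grDevices::gray.colors(64),
                        xlab = "frame", ylab = "ROI",
                        main = "ROI time-series carpet plot")
      }, title = "Carpet plot"))
    } else {
      panels <- c(panels, placeholder_panel("Carpet plot"))
    }
  }

  if (!is.null(motion)) {
    fdres <- framewise_displacement(motion)
    panels <- c(panels, panel_img(function() {
      graphics::plot(fdres$fd, type = "l", col = "firebrick",
                     xlab = "frame", ylab = "FD (mm)",
                     main = sprintf("Framewise displacement (mean %.3f mm)",
                                    fdres$mean))
    }, title = "Motion"))
  }

  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'/>\n",
    "<title>QC report: ", html_escape(subject), "</title>\n<style>\n",
    "body{font-family:sans-serif;margin:2em;}\n",
    "table.idp{border-collapse:collapse;}\n",
    "table.idp td,table.idp th{border:1px solid #999;padding:4px 10px;}\n",
    "tr.pass{background:#c8e6c9;} tr.fail{background:#ffcdd2;}\n",
    "tr.missing{background:#eeeeee;} tr.nothr{background:#ffffff;}\n",
    ".panel{display:inline-block;margin:1em;vertical-align:top;}\n",
    ".nodata{color:#777;font-style:italic;}\n",
    "</style></head><body>\n",
    "<h1>QC report: ", html_escape(subject), "</h1>\n",
    "<h2>Image-derived phenotypes</h2>\n", qc_table_html(qc), "\n",
    if (length(panels)) "<h2>Connectivity and motion panels</h2>\n" else "",
    paste(panels, collapse = "\n"), "\n</body></html>\n")
  writeLines(html, path)
  invisible(path)
}

#' Concatenate QC records across subjects as a group TSV
#'
#' @param records list of `qc_record` data frames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_group_table <- function(records, path) {
  all <- do.call(rbind, records)
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
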