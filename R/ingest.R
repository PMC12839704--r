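#' Load a report file and keep only its first page as an RGB raster
#'
#' Raster inputs (PNG, JPEG, single-page TIFF) are passed through; multi-page
#' TIFF documents are reduced to page 1, matching the convention that the
#' curves of interest sit on the first page of a spirometry report. Grayscale
#' input is promoted to three identical channels; an alpha channel is dropped.
#' A sidecar text layer (`<stem>.txt` next to the file) is attached when
#' present so that [parse_demographics()] can read the demographic block.
#'
#' PDF reports are not supported: rasterizing PDF requires a renderer that
#' this package deliberately does not depend on; export the report page as
#' PNG/TIFF (or supply the demographic sidecar) instead.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @param dpi Nominal resolution recorded on the page (default 150).
#' @return A `report_page`: `pixels` (h x w x 3 array in `[0, 1]`), `dpi`,
#'   `source_path`, and `text` (sidecar text layer or `NA`).
#' @export
rasterize_first_page <- function(path, dpi = 150L) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (length(pages) == 0L) stop("format error: TIFF has no pages",
                                    call. = FALSE)
      pages[[1]]   # only the first page is kept
    },
    jpg = ,
    jpeg = {
      img <- EBImage::readImage(path)
      d <- EBImage::imageData(img)
      if (length(dim(d)) == 2L) t(d) else aperm(d, c(2, 1, 3))
    },
    pdf = stop("format error: PDF input is not supported; export the first ",
               "page as PNG or TIFF", call. = FALSE),
    stop("format error: unsupported file type: .", ext, call. = FALSE))
  px <- ensure_rgb(px)
  if (dim(px)[1] < 200L || dim(px)[2] < 200L)
    stop("format error: page smaller than 200x200 px", call. = FALSE)
  sidecar <- sub(paste0("\\.", ext, "$"), ".txt", path, ignore.case = TRUE)
  text <- if (file.exists(sidecar))
    paste(readLines(sidecar, warn = FALSE), collapse = "\n") else NA_character_
  structure(list(pixels = px, dpi = dpi, source_path = path, text = text),
            class = "report_page")
}

#' @export
print.report_page <- function(x, ...) {
  cat("<report_page> ", dim(x$pixels)[1], "x", dim(x$pixels)[2], " px @ ",
      x$dpi, " dpi; text layer: ", !is.na(x$text), "\n", sep = "")
  invisible(x)
}

as_demographics <- function(x) {
  if (inherits(x, "demographics")) return(x)
  stopifnot(is.list(x), all(c("sex", "age", "bmi") %in% names(x)))
  sex <- normalize_sex_token(as.character(x$sex))
  age <- as.numeric(x$age); bmi <- as.numeric(x$bmi)
  if (!is.finite(age) || age <= 0) stop("age must be finite and positive",
                                        call. = FALSE)
  if (!is.finite(bmi) || bmi <= 0) stop("bmi must be finite and positive",
                                        call. = FALSE)
  structure(list(sex = sex, age = age, bmi = bmi), class = "demographics")
}

normalize_sex_token <- function(tok) {
  t <- tolower(trimws(tok))
  if (t %in% c("man", "male", "m", "hombre", "0")) return("man")
  if (t %in% c("woman", "female", "w", "f", "mujer", "1")) return("woman")
  stop("format error: unparseable sex token: \"", tok, "\"", call. = FALSE)
}

#' Parse the demographic fields from a report's text layer
#'
#' Accepts either a `report_page` (whose sidecar text layer is used) or a
#' character string. The grammar is labelled lines separated by newlines,
#' `/`, `;` or `|`: a field label (`sex`/`gender`, `age`, `bmi`), a `:` or
#' `=` separator, and the value. Decimal commas are normalized, unit suffixes
#' (years, kg/m2) are tolerated, and sex accepts
#' man/male/m/hombre/0 and woman/female/w/f/mujer/1.
#'
#' @param x A `report_page` or a character scalar.
#' @return A `demographics` object: `sex` (`"man"`/`"woman"`), `age` (years),
#'   `bmi` (kg/m2).
#' @examples
#' parse_demographics("Sex: Woman / Age: 45 / BMI: 18.1")
#' @export
parse_demographics <- function(x) {
  if (inherits(x, "report_page")) {
    if (is.na(x$text))
      stop("missing-field error: page has no text layer; supply a sidecar",
           call. = FALSE)
    x <- x$text
  }
  stopifnot(is.character(x), length(x) == 1L)
  # fields are separated by newlines, ";", "|" or a slash surrounded by
  # whitespace (a bare "/" may be part of a unit such as kg/m2)
  segs <- trimws(unlist(strsplit(x, "\n|;|\\||\\s+/\\s+")))
  segs <- segs[nzchar(segs)]
  fields <- list()
  for (s in segs) {
    mtc <- regmatches(s, regexec("^([A-Za-z]+)[^:=]*[:=]\\s*(.+)$", s))[[1]]
    if (length(mtc) != 3L) next
    key <- tolower(mtc[2]); val <- trimws(mtc[3])
    if (key %in% c("sex", "gender")) fields$sex <- val
    else if (key == "age") fields$age <- val
    else if (key == "bmi") fields$bmi <- val
  }
  for (f in c("sex", "age", "bmi"))
    if (is.null(fields[[f]]))
      stop("missing-field error: \"", f, "\" not found in text", call. = FALSE)
  num <- function(v) {
    v <- gsub(",", ".", v)
    v <- regmatches(v, regexpr("[0-9]+\\.?[0-9]*", v))
    as.numeric(v)
  }
  as_demographics(list(sex = normalize_sex_token(fields$sex),
                       age = num(fields$age), bmi = num(fields$bmi)))
}

#' @export
print.demographics <- function(x, ...) {
  cat("<demographics> sex = ", x$sex, ", age = ", x$age, " y, BMI = ",
      x$bmi, " kg/m2\n", sep = "")
  invisible(x)
}

#' Read a demographic sidecar CSV
#'
#' Sidecar format: columns `path, sex, age, bmi`; one row per report. Used
#' when a report carries no text layer.
#'
#' @param csv_path Path to the sidecar CSV.
#' @param report_path Report file whose row is wanted; `NULL` returns all rows.
#' @return A `demographics` object (or the full data.frame).
#' @export
read_sidecar <- function(csv_path, report_path = NULL) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("path", "sex", "age", "bmi")
  if (!all(need %in% names(df)))
    stop("format error: sidecar must have columns path, sex, age, bmi",
         call. = FALSE)
  if (is.null(report_path)) return(df)
  row <- df[basename(df$path) == basename(report_path), , drop = FALSE]
  if (nrow(row) == 0L)
    stop("missing-field error: no sidecar row for ", report_path,
         call. = FALSE)
  as_demographics(as.list(row[1, c("sex", "age", "bmi")]))
}
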