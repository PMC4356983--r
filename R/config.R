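#' Pipeline configuration files
#'
#' Every tunable knob of the pipeline lives in one structured text file
#' using a small YAML subset: nested maps by 2-space indentation, lists of
#' maps as `- ` items, scalars (numbers, booleans, quoted or bare strings)
#' and flow sequences like `[280, 360]`.  `read_config()` /
#' `write_config()` round-trip such files; `default_config()` returns the
#' full default tree, with which any user config is merged.
#'
#' @param path file path.
#' @param x nested list of scalars / lists.
#' @return `read_config()` and `default_config()` return a nested list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\\s*#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  indents <- nchar(sub("\\S.*$", "", lines))
  parsed <- .cfg_parse_block(lines, indents, 1L, length(lines), indents[1])
  parsed$value
}

.cfg_scalar <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "~" || s == "null") return(NULL)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- substr(s, 2, nchar(s) - 1)
    if (!grepl("\\S", inner)) return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    vals <- lapply(parts, .cfg_scalar)
    return(tryCatch(unlist(vals, use.names = FALSE), error = function(e) vals))
  }
  if (grepl('^".*"$', s) || grepl("^'.*'$", s)) return(substr(s, 2, nchar(s) - 1))
  if (s %in% c("true", "TRUE", "yes")) return(TRUE)
  if (s %in% c("false", "FALSE", "no")) return(FALSE)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}

# parse lines[from..to] all at indentation >= base; returns list(value=)
.cfg_parse_block <- function(lines, indents, from, to, base) {
  if (from > to) return(list(value = NULL))
  at_base <- which(indents[from:to] == base) + from - 1L
  first <- trimws(lines[at_base[1]])
  if (startsWith(first, "- ") || first == "-") {
    # sequence: each "- " item owns following deeper lines
    out <- list()
    for (i in seq_along(at_base)) {
      start <- at_base[i]
      end <- if (i < length(at_base)) at_base[i + 1] - 1L else to
      head <- sub("^\\s*-\\s?", "", lines[start])
      if (grepl(":", head)) {
        # map item whose first key is inline on the "- " line
        sub_lines <- c(paste0(strrep(" ", base + 2), head), lines[(start + 1):end])
        sub_ind <- c(base + 2L, indents[(start + 1):end])
        if (start == end) { sub_lines <- sub_lines[1]; sub_ind <- sub_ind[1] }
        out[[i]] <- .cfg_parse_block(sub_lines, sub_ind, 1L,
                                     length(sub_lines), base + 2L)$value
      } else {
        out[[i]] <- .cfg_scalar(head)
      }
    }
    return(list(value = out))
  }
  # mapping
  out <- list()
  for (i in seq_along(at_base)) {
    start <- at_base[i]
    end <- if (i < length(at_base)) at_base[i + 1] - 1L else to
    ln <- trimws(lines[start])
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0) stop("malformed config line: ", ln)
    key <- trimws(m[2])
    rest <- m[3]
    if (grepl("\\S", rest)) {
      val <- .cfg_scalar(rest)
      out[key] <- list(val)
    } else if (end > start) {
      out[[key]] <- .cfg_parse_block(lines, indents, start + 1L, end,
                                     indents[start + 1L])$value
    } else {
      out[key] <- list(NULL)
    }
  }
  list(value = out)
}

#' @rdname read_config
#' @export
write_config <- function(x, path) {
  emit <- function(x, indent) {
    pad <- strrep(" ", indent)
    out <- character(0)
    if (is.list(x) && (is.null(names(x)) || all(names(x) == ""))) {
      for (item in x) {
        if (is.list(item) && !is.null(names(item))) {
          sub <- emit(item, indent + 2)
          sub[1] <- paste0(pad, "- ", sub("^\\s*", "", sub[1]))
          out <- c(out, sub)
        } else {
          out <- c(out, paste0(pad, "- ", .cfg_fmt(item)))
        }
      }
    } else {
      for (k in names(x)) {
        v <- x[[k]]
        if (is.list(v) || (length(v) > 1 && !is.null(v))) {
          if (is.list(v)) {
            out <- c(out, paste0(pad, k, ":"), emit(v, indent + 2))
          } else {
            out <- c(out, paste0(pad, k, ": [",
                                 paste(vapply(v, .cfg_fmt, ""), collapse = ", "), "]"))
          }
        } else {
          out <- c(out, paste0(pad, k, ": ", .cfg_fmt(v)))
        }
      }
    }
    out
  }
  writeLines(emit(x, 0), path)
  invisible(path)
}

.cfg_fmt <- function(v) {
  if (is.null(v)) return("~")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(format(v, digits = 15, scientific = FALSE))
  v <- as.character(v)
  if (grepl("^[A-Za-z0-9_./%+-]+$", v)) v else paste0('"', v, '"')
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    correction = list(
      smoothing_scale = 50
    ),
    segmentation = list(
      nucleus_min_area = 40,
      nucleus_max_area = 2000,
      cell_expand_px = 2
    ),
    cell_qc = list(
      expression_k = 3,
      max_saturated_fraction = 0.01,
      cell_area_min = 200,
      cell_area_max = 4000,
      min_form_factor = 0.4
    ),
    image_qc = list(
      min_cells = 10,
      focus_gate = "adaptive",
      background_gate = "adaptive"
    ),
    plate_qc = list(
      max_failure_fraction = 0.75
    ),
    scoring = list(
      sem_multiplier = 2,
      aggregate = "mean",
      t_test = "student"
    ),
    io = list(
      filename_template = "{well}_f{field:02d}_ch{channel}.tif",
      channel_tokens = list(nuclei = "1", total = "2", surface = "3")
    )
  )
}

# deep-merge user config over defaults
.merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}
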