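#' @useDynLib siftscif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal PDBx/mmCIF reader/writer.
#
# A cif_doc is an ordered named list of categories; each category is a
# data.frame of character columns holding values verbatim ('.' and '?'
# included), so that write(read(x)) preserves content exactly.  Category
# names are stored without the leading underscore; item names without the
# category prefix.  Single data block only.
# ---------------------------------------------------------------------------

#' Read a PDBx/mmCIF file
#'
#' Parses a single-block mmCIF file into an ordered list of category tables.
#' Both `loop_` and key-value presentation are supported, as are quoted
#' values and semicolon-delimited text fields.  Values are kept verbatim as
#' character data; the null (`.`) and unknown (`?`) placeholders are not
#' converted.
#'
#' @param path Path to an mmCIF file.
#' @return An object of class `cif_doc`: a list with elements `block` (the
#'   data block code) and `categories` (named list of data.frames).
#' @export
cif_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- cif_tokenize(lines)
  cif_parse_tokens(toks, path)
}

# tokenizer: returns data.frame(token, forced, line); 'forced' marks quoted
# strings and text fields, which are always values even if they look like tags
cif_tokenize <- function(lines) {
  n <- length(lines)
  out_tok <- vector("list", n)
  out_forced <- vector("list", n)
  in_text <- FALSE
  text_buf <- NULL
  text_start <- 0L
  # fast path: lines with no quoting/comment/text-field machinery
  simple <- !grepl("['\";#]", lines, perl = TRUE)
  for (i in seq_len(n)) {
    line <- lines[[i]]
    if (in_text) {
      if (startsWith(line, ";")) {
        out_tok[[text_start]] <- paste(text_buf, collapse = "\n")
        out_forced[[text_start]] <- TRUE
        in_text <- FALSE
        rest <- substring(line, 2L)
        if (nzchar(trimws(rest))) stop("text after closing ';' at line ", i)
      } else {
        text_buf <- c(text_buf, line)
      }
      next
    }
    if (startsWith(line, ";")) {
      in_text <- TRUE
      text_start <- i
      text_buf <- substring(line, 2L)
      if (!nzchar(text_buf)) text_buf <- character(0)
      next
    }
    if (simple[[i]]) {
      tk <- strsplit(trimws(line), "[ \t]+")[[1]]
      tk <- tk[nzchar(tk)]
      if (length(tk)) {
        out_tok[[i]] <- tk
        out_forced[[i]] <- rep(FALSE, length(tk))
      }
      next
    }
    sc <- cif_scan_line(line, i)
    if (length(sc$token)) {
      out_tok[[i]] <- sc$token
      out_forced[[i]] <- sc$forced
    }
  }
  if (in_text) stop("unterminated text field starting at line ", text_start)
  lens <- lengths(out_tok)
  data.frame(token = unlist(out_tok, use.names = FALSE),
             forced = unlist(out_forced, use.names = FALSE),
             line = rep(seq_len(n), lens),
             stringsAsFactors = FALSE)
}

# character-level scan for lines containing quotes or comments
cif_scan_line <- function(line, lineno) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  len <- length(chars)
  tok <- character(0)
  forced <- logical(0)
  p <- 1L
  while (p <= len) {
    while (p <= len && chars[p] %in% c(" ", "\t")) p <- p + 1L
    if (p > len) break
    ch <- chars[p]
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      q <- p + 1L
      close_at <- NA_integer_
      while (q <= len) {
        if (chars[q] == ch && (q == len || chars[q + 1L] %in% c(" ", "\t"))) {
          close_at <- q
          break
        }
        q <- q + 1L
      }
      if (is.na(close_at)) stop("unterminated quoted value at line ", lineno)
      tok <- c(tok, if (close_at > p + 1L)
        paste(chars[(p + 1L):(close_at - 1L)], collapse = "") else "")
      forced <- c(forced, TRUE)
      p <- close_at + 1L
    } else {
      q <- p
      while (q <= len && !chars[q] %in% c(" ", "\t")) q <- q + 1L
      tok <- c(tok, paste(chars[p:(q - 1L)], collapse = ""))
      forced <- c(forced, FALSE)
      p <- q
    }
  }
  list(token = tok, forced = forced)
}

cif_parse_tokens <- function(toks, path) {
  token <- toks$token
  forced <- toks$forced
  lineno <- toks$line
  nt <- length(token)
  block <- ""
  cats <- list()
  is_tag <- !forced & startsWith(token, "_")
  is_ctrl <- !forced & (startsWith(token, "data_") | token == "loop_" |
                          token == "stop_" | startsWith(token, "save_"))
  j <- 1L
  add_items <- function(cat, items, values_mat) {
    df_new <- as.data.frame(values_mat, stringsAsFactors = FALSE)
    names(df_new) <- items
    if (is.null(cats[[cat]])) {
      cats[[cat]] <<- df_new
    } else {
      old <- cats[[cat]]
      if (nrow(old) != nrow(df_new))
        stop("category _", cat, " given with inconsistent row counts in ", path)
      cats[[cat]] <<- cbind(old, df_new)
    }
  }
  while (j <= nt) {
    if (is_ctrl[j] && startsWith(token[j], "data_")) {
      if (nzchar(block))
        stop("multiple data blocks in ", path, " (line ", lineno[j], ")")
      block <- substring(token[j], 6L)
      j <- j + 1L
    } else if (is_ctrl[j] && token[j] == "loop_") {
      j <- j + 1L
      items_full <- character(0)
      while (j <= nt && is_tag[j]) {
        items_full <- c(items_full, token[j])
        j <- j + 1L
      }
      if (!length(items_full))
        stop("loop_ without item names at line ", lineno[j - 1L], " in ", path)
      v0 <- j
      while (j <= nt && !is_tag[j] && !is_ctrl[j]) j <- j + 1L
      vals <- token[v0:(j - 1L)]
      k <- length(items_full)
      if (j - v0 == 0L || (j - v0) %% k != 0L)
        stop("loop_ row of wrong width near line ",
             lineno[min(j - 1L, nt)], " in ", path)
      mat <- matrix(vals, ncol = k, byrow = TRUE)
      sp <- cif_split_item(items_full, path, lineno[v0 - 1L])
      if (length(unique(sp$cat)) != 1L)
        stop("loop_ mixes categories at line ", lineno[v0 - 1L], " in ", path)
      add_items(sp$cat[1L], sp$item, mat)
    } else if (is_tag[j]) {
      if (j + 1L > nt)
        stop("item ", token[j], " without value at line ", lineno[j], " in ", path)
      sp <- cif_split_item(token[j], path, lineno[j])
      val <- token[j + 1L]
      if (!forced[j + 1L] && (is_tag[j + 1L] || is_ctrl[j + 1L]))
        stop("item ", token[j], " without value at line ", lineno[j], " in ", path)
      add_items(sp$cat, sp$item, matrix(val, nrow = 1L))
      j <- j + 2L
    } else {
      stop("unexpected token '", token[j], "' at line ", lineno[j], " in ", path)
    }
  }
  structure(list(block = block, categories = cats), class = "cif_doc")
}

cif_split_item <- function(full, path, lineno) {
  if (!all(grepl("^_[^.]+\\.[^.]+$", full)))
    stop("malformed item name '", full[!grepl("^_[^.]+\\.", full)][1L],
         "' at line ", lineno, " in ", path)
  dot <- regexpr(".", full, fixed = TRUE)
  list(cat = substring(full, 2L, dot - 1L),
       item = substring(full, dot + 1L))
}

#' Write a PDBx/mmCIF document
#'
#' Serializes a `cif_doc` back to text.  Multi-row categories use `loop_`
#' syntax; single-row categories are written as key-value pairs.  Values
#' containing whitespace or quote characters are quoted; values containing
#' newlines become semicolon text fields.  The writer is deterministic, so
#' write -> read -> write is a fixpoint.
#'
#' @param doc A `cif_doc`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
cif_write <- function(doc, path) {
  stopifnot(inherits(doc, "cif_doc"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("data_", doc$block), con)
  writeLines("#", con)
  for (cat in names(doc$categories)) {
    df <- doc$categories[[cat]]
    if (is.null(df) || nrow(df) == 0L) next
    if (nrow(df) == 1L) {
      tags <- paste0("_", cat, ".", names(df))
      width <- max(nchar(tags))
      for (k in seq_along(df)) {
        v <- cif_quote(as.character(df[1L, k]))
        if (startsWith(v, "\n;")) {
          writeLines(tags[k], con)
          writeLines(substring(v, 2L), con)
        } else {
          writeLines(sprintf("%-*s %s", width, tags[k], v), con)
        }
      }
    } else {
      writeLines("loop_", con)
      writeLines(paste0("_", cat, ".", names(df)), con)
      cols <- lapply(df, function(col) vapply(as.character(col), cif_quote, "",
                                              USE.NAMES = FALSE))
      mat <- do.call(cbind, cols)
      multi <- grepl("\n;", mat, fixed = TRUE)
      if (any(multi)) {
        # rows containing text-field values are emitted token-wise
        for (r in seq_len(nrow(mat))) {
          buf <- character(0)
          for (k in seq_len(ncol(mat))) {
            v <- mat[r, k]
            if (startsWith(v, "\n;")) {
              if (length(buf)) writeLines(paste(buf, collapse = " "), con)
              buf <- character(0)
              writeLines(substring(v, 2L), con)
            } else buf <- c(buf, v)
          }
          if (length(buf)) writeLines(paste(buf, collapse = " "), con)
        }
      } else {
        writeLines(do.call(paste, c(as.data.frame(mat, stringsAsFactors = FALSE),
                                    list(sep = " "))), con)
      }
    }
    writeLines("#", con)
  }
  invisible(path)
}

cif_quote <- function(v) {
  if (is.na(v) || !nzchar(v)) return(".")
  if (grepl("\n", v, fixed = TRUE)) return(paste0("\n;", v, "\n;"))
  needs <- grepl("[ \t'\"]", v) || v %in% c("loop_", "stop_", "global_") ||
    startsWith(v, "_") || startsWith(v, "#") || startsWith(v, "data_") ||
    startsWith(v, "save_") || startsWith(v, "$") || startsWith(v, "[")
  if (!needs) return(v)
  if (!grepl("'", v, fixed = TRUE)) return(paste0("'", v, "'"))
  if (!grepl("\"", v, fixed = TRUE)) return(paste0("\"", v, "\""))
  paste0("\n;", v, "\n;")
}

# '.'/'?' -> NA at the domain boundary
cif_null <- function(x) {
  x[x %in% c(".", "?")] <- NA_character_
  x
}
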