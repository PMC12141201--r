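## SMILES tokenizer / syntax validator
##
## OpenBabel (the canonicalization backend) is lenient: it silently repairs
## inputs such as "C(C". The library-reading contract requires malformed
## records to be skipped and counted, so well-formedness is checked here
## before any chemistry is delegated to the backend. This is a validator and
## token extractor only — aromaticity perception, canonical ordering and all
## real chemistry stay with OpenBabel.

SMI_ORGANIC <- c("Br", "Cl", "B", "C", "N", "O", "P", "S", "F", "I",
                 "b", "c", "n", "o", "p", "s")
SMI_BRACKET_RE <- paste0(
  "^\\[([0-9]+)?",                        # isotope
  "([A-Z][a-z]?|[bcnops]|se|as|\\*)",     # element (aromatic lowercase allowed)
  "(@@?|@TH[12]|@AL[12]|@SP[1-3])?",      # chirality
  "(H[0-9]*)?",                           # explicit H count
  "(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?", # formal charge
  "(:[0-9]+)?\\]$"                        # atom-map class
)

## Tokenize one SMILES string. Returns a data.frame with one row per atom
## (element, aromatic, charge, hcount — NA when implicit) or NULL when the
## string is not well-formed.
smiles_tokenize <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) return(NULL)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  i <- 1
  depth <- 0
  open_rings <- character(0)
  pending_bond <- FALSE
  last_was_atom <- FALSE
  atoms <- list()

  push_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_) {
    atoms[[length(atoms) + 1]] <<- list(element = element, aromatic = aromatic,
                                        charge = charge, hcount = hcount)
    pending_bond <<- FALSE
    last_was_atom <<- TRUE
  }

  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) return(NULL)                       # unterminated bracket
      tok <- paste(chars[i:j], collapse = "")
      m <- regmatches(tok, regexec(SMI_BRACKET_RE, tok))[[1]]
      if (length(m) == 0) return(NULL)
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      element <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      hs <- m[5]
      hcount <- if (!nzchar(hs)) 0L
      else if (hs == "H") 1L else as.integer(substr(hs, 2, nchar(hs)))
      chs <- m[6]
      charge <- if (!nzchar(chs)) 0L
      else if (grepl("^[+-][0-9]+$", chs))
        as.integer(chs)
      else
        nchar(chs) * (if (substr(chs, 1, 1) == "+") 1L else -1L)
      push_atom(element, aromatic, charge, hcount)
      i <- j + 1
    } else if (two %in% c("Br", "Cl")) {
      push_atom(two, FALSE); i <- i + 2
    } else if (ch %in% SMI_ORGANIC) {
      aromatic <- ch %in% c("b", "c", "n", "o", "p", "s")
      push_atom(if (aromatic) toupper(ch) else ch, aromatic)
      i <- i + 1
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      if (pending_bond) return(NULL)                # two bonds in a row
      pending_bond <- TRUE
      last_was_atom <- FALSE
      i <- i + 1
    } else if (ch == "(") {
      if (!last_was_atom) return(NULL)              # branch needs an atom before it
      depth <- depth + 1
      last_was_atom <- FALSE
      i <- i + 1
    } else if (ch == ")") {
      depth <- depth - 1
      if (depth < 0 || pending_bond) return(NULL)
      last_was_atom <- TRUE                         # chain resumes at parent atom
      i <- i + 1
    } else if (ch == ".") {
      if (pending_bond) return(NULL)
      last_was_atom <- FALSE
      i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (!last_was_atom && !pending_bond) return(NULL)
      if (ch == "%") {
        if (i + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2])))
          return(NULL)
        lab <- paste0(chars[i + 1], chars[i + 2]); i <- i + 3
      } else {
        lab <- ch; i <- i + 1
      }
      if (lab %in% open_rings) open_rings <- setdiff(open_rings, lab)
      else open_rings <- c(open_rings, lab)
      pending_bond <- FALSE
    } else {
      return(NULL)                                  # unknown character
    }
  }
  if (depth != 0 || pending_bond || length(open_rings) > 0) return(NULL)
  if (length(atoms) == 0) return(NULL)
  do.call(rbind, lapply(atoms, function(a)
    data.frame(element = a$element, aromatic = a$aromatic,
               charge = a$charge, hcount = a$hcount,
               stringsAsFactors = FALSE)))
}

#' Check whether SMILES strings are syntactically well-formed
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector, `TRUE` where the string tokenizes cleanly.
#' @export
#' @examples
#' smiles_is_valid(c("CCO", "c1ccccc1", "C(C"))
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) !is.null(smiles_tokenize(s)), logical(1),
         USE.NAMES = FALSE)
}
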