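## unit-length type names (1-10 bp) and the catalog id prefixes used in
## published SSR tables of this kind
ssr_type_names <- c("mono", "di", "tri", "tetra", "penta",
                    "hexa", "hepta", "octa", "nona", "deca")
ssr_id_prefixes <- c(mono = "M", di = "D", tri = "T", tetra = "Te",
                     penta = "P", hexa = "H", hepta = "cHp", octa = "O",
                     nona = "N", deca = "De")
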