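>Pc1e_precursor delta-paraponeritoxin-Pc1e precursor (signal 1-24, propeptide 25-38, mature 39-65)
MRIGKLILISVAIIAIMISDPVKSEAVAKPSAEAVSEAFLPLLILGSLLMTPPVIQAIHD
VQRGK
>Pc1a_mature published mature poneratoxin (UniProt P41736)
FLPLLILGSLLMTPPVIQAIHDAQR
>Pc1d_mature Peruvian isoform, mature peptide (reconstructed from the published Pc1a isoform set)
FLPLLILGSLLMTPPVIQAIHDAQR
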