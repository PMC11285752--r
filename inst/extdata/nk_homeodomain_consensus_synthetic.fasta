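>nk_homeodomain_consensus_synthetic a 60-residue NK-class homeodomain consensus stand-in (synthetic; not taken from any published motif set)
KRKRRVLFTKAQTYELERRFRQQRYLSAPEREHLASLIRLTPTQVKIWFQNHRYKMKRAR
>tn_domain_synthetic NK2-family TN-domain-like decapeptide stand-in (synthetic)
MRLSSPEPAV
>nk2_box_synthetic NK2-box-like peptide stand-in (synthetic)
QAQVWFQNRRAKWRK
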