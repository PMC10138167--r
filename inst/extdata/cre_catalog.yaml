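# Default catalog of stress-related cis-regulatory elements used by the
# promoter scanner. The source study reports element names only; the
# consensus strings below follow common PlantCARE conventions and are
# editable defaults, not study-derived ground truth. IUPAC ambiguity codes
# are allowed in `consensus`.
elements:
  - name: ARE
    description: anaerobic induction element
    consensus: AAACCA
    both_strands: true
  - name: WRE3
    description: wound-responsive element 3
    consensus: CCACCT
    both_strands: true
  - name: WUN
    description: wound-responsive motif
    consensus: AAATTTCCT
    both_strands: true
  - name: STRE
    description: general stress response element
    consensus: AGGGG
    both_strands: true
  - name: LTR
    description: low-temperature responsiveness element
    consensus: CCGAAA
    both_strands: true
  - name: MBS
    description: MYB binding site, drought inducibility
    consensus: CAACTG
    both_strands: true
  - name: DRE
    description: dehydration-responsive element core
    consensus: GCCGAC
    both_strands: true
  - name: AT-rich
    description: elicitor-mediated activation element
    consensus: ATAGAAATCAA
    both_strands: true
  - name: TC-rich
    description: defense and stress responsiveness repeats
    consensus: GTTTTCTTAC
    both_strands: true
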