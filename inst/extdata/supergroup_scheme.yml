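# Lineage-marker -> supergroup rules, first match wins (priority order).
# Cyanobacteria must precede the generic Bacteria rule; Fungi and Metazoa
# must precede the Opisthokonta fallback; bare Eukaryota is the last
# resort bin.
rules:
  - label: Viridiplantae
    markers: [Viridiplantae]
  - label: Fungi
    markers: [Fungi]
  - label: Metazoa
    markers: [Metazoa]
  - label: Other_Opisthokonta
    markers: [Opisthokonta, Choanoflagellata]
  - label: Amoebozoa
    markers: [Amoebozoa]
  - label: Excavata
    markers: [Excavata, Discoba, Metamonada]
  - label: SAR
    markers: [Sar, SAR, Stramenopiles, Stramenopila, Alveolata, Rhizaria]
  - label: Cyanobacteria
    markers: [Cyanobacteriota, Cyanobacteria]
  - label: Other_Bacteria
    markers: [Bacteria]
  - label: Archaea
    markers: [Archaea]
  - label: Viruses
    markers: [Viruses, Viroids]
  - label: Other_Eukaryota
    markers: [Eukaryota]
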