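# Default 7TM bundle frame: 200 Ballesteros-Weinstein positions over seven
# helices, five sections per helix (section 1 = extracellular, 5 =
# intracellular). Ranges and section boundaries are editable; the shipped
# values satisfy the published combinatorics of the 200-residue frame
# (helix III 3.22-3.55 with sections 8,8,4,7,7; I.1 = 3, VI.1 = 10,
# VII.1 = 9, VII.5 = 3 positions; 193 adjacent pairs).
helices:
  - {helix: 1, start: 30, end: 60, sections: [3, 7, 7, 7, 7], extracellular_end: first}
  - {helix: 2, start: 38, end: 67, sections: [6, 6, 6, 6, 6], extracellular_end: last}
  - {helix: 3, start: 22, end: 55, sections: [8, 8, 4, 7, 7], extracellular_end: first}
  - {helix: 4, start: 39, end: 62, sections: [5, 5, 5, 5, 4], extracellular_end: last}
  - {helix: 5, start: 36, end: 64, sections: [6, 6, 6, 6, 5], extracellular_end: first}
  - {helix: 6, start: 30, end: 60, sections: [10, 6, 5, 5, 5], extracellular_end: last}
  - {helix: 7, start: 33, end: 53, sections: [9, 3, 3, 3, 3], extracellular_end: first}
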