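# Anchor compositions of the geometric residue-type code table.
# For each residue type: number of virtual atoms placed on each
# backbone anchor (N, CA, C, O). Override entries and pass the file
# to code_table() to match an external convention.
ALA: {"N": 9, "CA": 0, "C": 0, "O": 0}
ARG: {"N": 3, "CA": 0, "C": 0, "O": 0}
ASN: {"N": 6, "CA": 0, "C": 0, "O": 0}
ASP: {"N": 5, "CA": 0, "C": 0, "O": 1}
CYS: {"N": 8, "CA": 0, "C": 0, "O": 0}
GLN: {"N": 5, "CA": 0, "C": 0, "O": 0}
GLU: {"N": 4, "CA": 0, "C": 0, "O": 1}
GLY: {"N": 10, "CA": 0, "C": 0, "O": 0}
HIS: {"N": 4, "CA": 0, "C": 0, "O": 0}
ILE: {"N": 5, "CA": 1, "C": 0, "O": 0}
LEU: {"N": 5, "CA": 0, "C": 1, "O": 0}
LYS: {"N": 4, "CA": 1, "C": 0, "O": 0}
MET: {"N": 4, "CA": 0, "C": 0, "O": 2}
PHE: {"N": 2, "CA": 0, "C": 0, "O": 1}
PRO: {"N": 0, "CA": 0, "C": 0, "O": 7}
SER: {"N": 7, "CA": 0, "C": 0, "O": 1}
THR: {"N": 3, "CA": 0, "C": 0, "O": 4}
TRP: {"N": 0, "CA": 0, "C": 0, "O": 0}
TYR: {"N": 2, "CA": 0, "C": 0, "O": 0}
VAL: {"N": 7, "CA": 0, "C": 0, "O": 0}
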