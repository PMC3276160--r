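>ref
TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTGAGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT
>strain1
TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTGAGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT
>strain2
TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTGAGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT
>strain3
TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTGGGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT
>strain4
TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTGGGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT
>strain5
TTGCGTGCGCAACGGCCTGTTCAATCGTGGCGCACGGCACACTCACGTCCATTTTACCTGGGATTGCGATAATGGCCACTGGATGCGTTATACTCAGTATTACTCTTCAACACCTAATCT
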