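name: GH
chromosome: 12
inheritance: autosomal
length: 1971
functional_class: functional_gene
coding: 101-748:1:+

name: APOB
chromosome: 3
inheritance: autosomal
length: 645
functional_class: functional_gene
coding: 101-273:1:+

name: CASQ1
chromosome: 4
inheritance: autosomal
length: 583
functional_class: functional_gene
coding: 101-231:1:+

name: CNTF
chromosome: 2
inheritance: autosomal
length: 759
functional_class: functional_gene
coding: 101-214:1:+

name: MTNR1B
chromosome: 9
inheritance: autosomal
length: 568
functional_class: functional_gene
coding: 101-420:1:+

name: PIT1
chromosome: 13
inheritance: autosomal
length: 650
functional_class: functional_gene
coding: 101-311:1:+

name: PYG
chromosome: 2
inheritance: autosomal
length: 578
functional_class: functional_gene
coding: 101-201:1:+

name: SKM
chromosome: 1
inheritance: autosomal
length: 784
functional_class: functional_gene
coding: 101-274:1:+

name: BCNTP
chromosome: 1
inheritance: autosomal
length: 669
functional_class: pseudogene

name: UCP1P
chromosome: 8
inheritance: autosomal
length: 635
functional_class: pseudogene

name: CH4
chromosome: 4
inheritance: autosomal
length: 350
functional_class: intergenic

name: CH7
chromosome: 7
inheritance: autosomal
length: 641
functional_class: intergenic

name: CH11
chromosome: 11
inheritance: autosomal
length: 506
functional_class: intergenic

name: CH14
chromosome: 14
inheritance: autosomal
length: 520
functional_class: intergenic
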