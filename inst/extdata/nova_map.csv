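food,class
rice,MPF
green leaves,MPF
vegetables,MPF
vegetable soup,MPF
beans,MPF
cassava flour,MPF
corn/potatoes/mashed potatoes,MPF
pasta,MPF
beef/poultry,MPF
eggs,MPF
fish/seafood,MPF
fruit,MPF
porridge,MPF
coffee with milk,MPF
milk,MPF
plain cake,MPF
bread,PF
cheese,PF
instant pasta,UPF
french fries,UPF
sausages,UPF
cheese bread,UPF
cream cookies,UPF
breakfast cereal,UPF
yogurt,UPF
chocolate milk,UPF
fruit juices,UPF
sodas,UPF
sweets,UPF
packaged snacks,UPF
pizza/hamburger/hot dog,UPF
nuggets,UPF
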