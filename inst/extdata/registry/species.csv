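code,scientific_name,family,growth_form,decay_group
ABCO,Abies concolor,Pinaceae,tree,fir
ABMA,Abies magnifica,Pinaceae,tree,fir
ABPR,Abies procera,Pinaceae,tree,fir
PILA,Pinus lambertiana,Pinaceae,tree,pine
PIPO,Pinus ponderosa,Pinaceae,tree,pine
PSME,Pseudotsuga menziesii,Pinaceae,tree,fir
CADE,Calocedrus decurrens,Cupressaceae,tree,cedar
CONU,Cornus nuttallii,Cornaceae,tree,hardwood
QUKE,Quercus kelloggii,Fagaceae,tree,hardwood
PRSP,Prunus spp.,Rosaceae,tree,hardwood
SASC,Salix scouleriana,Salicaceae,tree,hardwood
RHCA,Rhamnus californica,Rhamnaceae,tree,hardwood
UNKN,Unknown,Unknown,tree,unknown
ARPA,Arctostaphylos patula,Ericaceae,shrub,hardwood
CECO,Ceanothus cordulatus,Rhamnaceae,shrub,hardwood
CEIN,Ceanothus integerrimus,Rhamnaceae,shrub,hardwood
CEPA,Ceanothus parvifolius,Rhamnaceae,shrub,hardwood
CHSE,Chrysolepis sempervirens,Fagaceae,shrub,hardwood
COCO,Corylus cornuta var. californica,Betulaceae,shrub,hardwood
COSE,Cornus sericea,Cornaceae,shrub,hardwood
LEDA,Leucothoe davisiae,Ericaceae,shrub,hardwood
VAUL,Vaccinium uliginosum,Ericaceae,shrub,hardwood
SARA,Sambucus racemosa,Adoxaceae,shrub,hardwood
RHOC,Rhododendron occidentale,Ericaceae,shrub,hardwood
RINE,Ribes nevadense,Grossulariaceae,shrub,hardwood
RIRO,Ribes roezlii,Grossulariaceae,shrub,hardwood
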