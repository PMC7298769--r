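<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:simpleType name="identifier">
    <xs:restriction base="xs:string">
      <xs:pattern value="[A-Za-z_][A-Za-z0-9_.-]*"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="workflow">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="settings" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="constants" minOccurs="0">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="constant" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:simpleContent>
                          <xs:extension base="xs:string">
                            <xs:attribute name="name" type="identifier" use="required"/>
                          </xs:extension>
                        </xs:simpleContent>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="wrappers" minOccurs="0">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="wrapper" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="name" type="identifier" use="required"/>
                        <xs:attribute name="kind" use="required">
                          <xs:simpleType>
                            <xs:restriction base="xs:string">
                              <xs:enumeration value="identity"/>
                              <xs:enumeration value="prefix"/>
                              <xs:enumeration value="package_manager"/>
                              <xs:enumeration value="container"/>
                            </xs:restriction>
                          </xs:simpleType>
                        </xs:attribute>
                        <xs:attribute name="prefix" type="xs:string"/>
                        <xs:attribute name="command" type="xs:string"/>
                        <xs:attribute name="runtime" type="xs:string"/>
                        <xs:attribute name="autoMount" type="xs:boolean"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="executors" minOccurs="0">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="executor" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="name" type="identifier" use="required"/>
                        <xs:attribute name="kind" use="required">
                          <xs:simpleType>
                            <xs:restriction base="xs:string">
                              <xs:enumeration value="local"/>
                              <xs:enumeration value="spool"/>
                            </xs:restriction>
                          </xs:simpleType>
                        </xs:attribute>
                        <xs:attribute name="maxSlots" type="xs:positiveInteger"/>
                        <xs:attribute name="packageManager" type="identifier"/>
                        <xs:attribute name="container" type="identifier"/>
                        <xs:attribute name="spoolDir" type="xs:string"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="tasks">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="task" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="depends" type="identifier" minOccurs="0" maxOccurs="unbounded"/>
                    <xs:element name="param" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:simpleContent>
                          <xs:extension base="xs:string">
                            <xs:attribute name="name" type="identifier" use="required"/>
                          </xs:extension>
                        </xs:simpleContent>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="processBlock" minOccurs="0">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="column" type="identifier" minOccurs="0" maxOccurs="unbounded"/>
                          <xs:element name="row" minOccurs="0" maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:sequence>
                                <xs:element name="cell" type="xs:string" maxOccurs="unbounded"/>
                              </xs:sequence>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                        <xs:attribute name="kind" use="required">
                          <xs:simpleType>
                            <xs:restriction base="xs:string">
                              <xs:enumeration value="list"/>
                              <xs:enumeration value="folder"/>
                            </xs:restriction>
                          </xs:simpleType>
                        </xs:attribute>
                        <xs:attribute name="base" type="xs:string"/>
                        <xs:attribute name="pattern" type="xs:string"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="id" type="identifier" use="required"/>
                  <xs:attribute name="name" type="xs:string"/>
                  <xs:attribute name="module" type="identifier" use="required"/>
                  <xs:attribute name="version" type="xs:positiveInteger"/>
                  <xs:attribute name="executor" type="identifier" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
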